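Package: redese
Title: Sampling and Approximate Counting of Restricted Bipartite Degree
    Sequence Realizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Degree-preserving null models for bipartite and directed
    networks with forbidden edges. Implements the swap Markov chain on
    realizations of bipartite degree sequences whose forbidden edge set is
    a partial 1-factor plus a star (the '1F1S' restriction covering, in
    particular, loop-free directed graphs through their bipartite
    representation): a generalized Havel-type greedy construction with a
    full graphicality test, forbidden-set-compatible C4 and C6 swap moves,
    constructive connectivity of the realization space through alternating
    circuit decomposition, a lazy uniform-stationary Markov chain sampler,
    an exact backtracking enumerator, and a self-reduction approximate
    counter driven by the sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
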