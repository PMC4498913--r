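#' Read / write a problem as JSON
#'
#' Schema: `{"u": [{"label", "degree"}, ...], "w": [...],`
#' `"forbidden": [[u, w], ...], "star_center": optional}`. Reading validates
#' through [validate_problem()]; writing a validated problem and reading it
#' back is the identity.
#'
#' @param path file path.
#' @param problem a validated problem.
#' @return `read_problem` returns a validated problem; `write_problem`
#'   returns `path` invisibly.
#' @export
read_problem <- function(path) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) redese_stop("REJECT_SCHEMA",
                                                paste0("cannot parse JSON: ", conditionMessage(e))))
  side <- function(key) {
    recs <- x[[key]]
    if (is.null(recs) || !length(recs))
      redese_stop("REJECT_SCHEMA", sprintf("missing or empty '%s' array", key))
    lab <- vapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      if (is.null(r$label))
        redese_stop("REJECT_SCHEMA", sprintf("%s[%d]: missing 'label'", key, i))
      as.character(r$label)
    }, character(1L))
    deg <- vapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      if (is.null(r$degree))
        redese_stop("REJECT_SCHEMA", sprintf("%s[%d] ('%s'): missing 'degree'", key, i, recs[[i]]$label))
      as.numeric(r$degree)
    }, numeric(1L))
    list(lab = lab, deg = deg)
  }
  u <- side("u"); w <- side("w")
  fb <- NULL
  if (!is.null(x$forbidden) && length(x$forbidden)) {
    fb <- do.call(rbind, lapply(seq_along(x$forbidden), function(i) {
      pr <- x$forbidden[[i]]
      if (length(pr) != 2L)
        redese_stop("REJECT_SCHEMA", sprintf("forbidden[%d]: expected a pair", i))
      c(as.character(pr[[1L]]), as.character(pr[[2L]]))
    }))
  }
  validate_problem(u$lab, w$lab, u$deg, w$deg, fb,
                   star_center = if (!is.null(x$star_center)) as.character(x$star_center))
}

#' @rdname read_problem
#' @export
write_problem <- function(problem, path) {
  p <- problem
  x <- list(
    u = lapply(p$u, function(l) list(label = l, degree = unname(p$du[[l]]))),
    w = lapply(p$w, function(l) list(label = l, degree = unname(p$dw[[l]]))),
    forbidden = if (nrow(p$forbidden))
      lapply(seq_len(nrow(p$forbidden)), function(i) as.list(p$forbidden[i, ])) else list()
  )
  if (!is.na(p$star_center)) x$star_center <- p$star_center
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write a realization as an edge-list TSV
#'
#' Two tab-separated columns (`u` label, `w` label), one edge per line, no
#' header. Reading validates against the problem and reports the first
#' violated constraint (`INVALID_REALIZATION`).
#'
#' @param path file path.
#' @param problem the problem the edge list realizes.
#' @param realization a realization.
#' @export
read_realization <- function(path, problem) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  e <- if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      redese_stop("INVALID_REALIZATION",
                  sprintf("line %d does not have two tab-separated fields",
                          which(lengths(parts) != 2L)[1L]))
    do.call(rbind, parts)
  } else matrix(character(), 0L, 2L)
  new_realization(problem, e, validate = TRUE)
}

#' @rdname read_realization
#' @export
write_realization <- function(realization, path) {
  writeLines(paste(realization$edges[, 1L], realization$edges[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Export the biadjacency matrix as CSV
#'
#' Rows are `U` in input order, columns `W` in input order (row-major
#' top-down orientation).
#' @param realization a realization.
#' @param path file path.
#' @export
write_biadjacency <- function(realization, path) {
  utils::write.csv(biadjacency(realization), path)
  invisible(path)
}

#' Write sampled realizations as JSONL
#'
#' First record is a metadata header (`type`, `seed`, `steps`, `burn_in`,
#' `thin`), then one record `{"edges": [[u, w], ...]}` per sample.
#' @param samples list of realizations.
#' @param path file path.
#' @param meta named list merged into the header record.
#' @export
write_samples <- function(samples, path, meta = list()) {
  hdr <- jsonlite::toJSON(c(list(type = "redese_samples"), meta), auto_unbox = TRUE)
  recs <- vapply(samples, function(s) {
    ed <- lapply(seq_len(nrow(s$edges)), function(i) as.list(unname(s$edges[i, ])))
    as.character(jsonlite::toJSON(list(edges = ed), auto_unbox = TRUE))
  }, character(1L))
  writeLines(c(as.character(hdr), recs), path)
  invisible(path)
}

#' Write a swap-move sequence as JSONL
#'
#' One record `{"kind", "u", "w", "removed", "added"}` per move.
#' @param moves list of swap moves.
#' @param path file path.
#' @export
write_moves <- function(moves, path) {
  recs <- vapply(moves, function(m) {
    as.character(jsonlite::toJSON(list(
      kind = m$kind, u = m$u, w = m$w,
      removed = lapply(seq_len(nrow(m$removed)), function(i) as.list(unname(m$removed[i, ]))),
      added = lapply(seq_len(nrow(m$added)), function(i) as.list(unname(m$added[i, ])))
    ), auto_unbox = TRUE))
  }, character(1L))
  writeLines(recs, path)
  invisible(path)
}

#' Read / write directed degree sequences as TSV
#'
#' Columns `label`, `out_degree`, `in_degree`, with header.
#' @param path file path.
#' @param dds a [directed_degree_sequence()].
#' @export
read_directed_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "integer", "integer"))
  need <- c("label", "out_degree", "in_degree")
  if (!all(need %in% names(df)))
    redese_stop("REJECT_SCHEMA",
                sprintf("directed TSV needs columns %s", paste(need, collapse = ", ")))
  directed_degree_sequence(df$label, df$out_degree, df$in_degree)
}

#' @rdname read_directed_tsv
#' @export
write_directed_tsv <- function(dds, path) {
  utils::write.table(data.frame(label = dds$labels,
                                out_degree = unname(dds$out_degree),
                                in_degree = unname(dds$in_degree)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write arcs as TSV
#' @param arcs two-column matrix (`from`, `to`).
#' @param path file path.
#' @export
write_arcs_tsv <- function(arcs, path) {
  utils::write.table(as.data.frame(arcs), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
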