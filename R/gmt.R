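#' Read a GMT gene-set collection
#'
#' One set per line: set name, description, then tab-separated member
#' symbols. Duplicate members within a set are dropped; a line with fewer
#' than three tab-separated fields, or with no members, is an error naming
#' the offending line.
#'
#' @param path path to a `.gmt` file.
#' @return a named list of character vectors (set name -> member symbols).
#' @export
read_gmt <- function(path) {
  ln <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(ln))
  ln <- ln[keep]
  lineno <- which(keep)
  parts <- strsplit(ln, "\t", fixed = TRUE)
  sets <- vector("list", length(parts))
  nms <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L)
      stop("malformed GMT line ", lineno[i], " in ", path,
           ": fewer than 3 tab-separated fields")
    members <- unique(p[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop("empty gene set at GMT line ", lineno[i], " in ", path)
    nms[i] <- p[1]
    sets[[i]] <- members
  }
  if (anyDuplicated(nms))
    stop("duplicate set names in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional per-set description column (defaults to the
#'   set names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}
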