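# Local gene-set over-representation analysis: hypergeometric upper-tail
# tests of a candidate gene list against GMT collections, BH-adjusted.

#' Read a GMT gene-set collection
#'
#' Standard GMT lines: set name, description, then member gene symbols.
#' Symbols are upper-cased and deduplicated; lines with fewer than three
#' fields are skipped with a warning. The universe defaults to the union of
#' all set members.
#'
#' @param path GMT file path.
#' @param name collection name (defaults to the file name).
#' @return list of class `gene_set_collection` with `name`, `sets` (named
#'   list of gene vectors), `descriptions`, `universe`.
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    warnf("skipped %d GMT line(s) with fewer than 3 fields", sum(short))
    fields <- fields[!short]
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  descriptions <- vapply(fields, `[`, character(1), 2L)
  names(descriptions) <- names(sets)
  structure(list(name = name, sets = sets, descriptions = descriptions,
                 universe = sort(unique(unlist(sets)))),
            class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection` to write.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(s) {
    paste(c(s, collection$descriptions[[s]] %||% "na", collection$sets[[s]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each set, tests whether the query list overlaps it more than chance
#' given the universe: `p = P(X >= overlap)` for `X` hypergeometric with
#' universe size `N`, set size `K` and query size `n`. Query genes outside
#' the universe are dropped with a warning. q-values are BH across sets;
#' a set is called significant at adjusted p < 0.05.
#'
#' @param query character vector of gene symbols (candidate genes).
#' @param collection a [read_gmt()] collection.
#' @param universe optional universe override.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame ordered by q then p with columns `set`, `set_size`,
#'   `overlap`, `overlap_genes`, `p`, `q`, `significant`.
#' @export
ora <- function(query, collection, universe = NULL, alpha = 0.05) {
  universe <- universe %||% collection$universe
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warnf("dropping %d query gene(s) outside the universe: %s",
          length(outside), paste(outside, collapse = ", "))
    query <- setdiff(query, outside)
  }
  if (length(query) == 0L)
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), overlap_genes = character(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(s) {
    members <- intersect(collection$sets[[s]], universe)
    K <- length(members)
    hit <- intersect(query, members)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, set_size = K, overlap = k,
               overlap_genes = paste(sort(hit), collapse = ","),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < alpha
  out <- out[order(out$q, out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
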