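#' Literature co-occurrence evidence for candidate miRNAs
#'
#' For each miRNA, queries PubMed (through the supplied fetcher) for
#' records mentioning both the miRNA id and the disease name —
#' co-occurrence only, no relation extraction. miRNAs with zero hits are
#' retained with empty id lists. A fetcher failure for one miRNA is
#' recorded in that row's `status` and leaves the other rows unaffected;
#' the table is then marked partial.
#'
#' @param mirnas Character vector of miRNA ids to query.
#' @param disease_name Non-empty disease name.
#' @param fetcher A function `(mirna_id, disease_name) -> character vector
#'   of PubMed ids`. Use [pubmed_fetcher()] for live NCBI E-utilities
#'   access, or a stub for offline use.
#' @return An `evidence_table` data frame with columns `mirna_id`,
#'   `pubmed_ids` (list column of unique numeric-string ids), `n_hits`,
#'   `status` (`"ok"` or the error message); attributes `disease_name`,
#'   `retrieved_at` and `partial`.
#' @export
search_evidence <- function(mirnas, disease_name, fetcher) {
  if (!is.function(fetcher)) stop("fetcher must be a function", call. = FALSE)
  if (!is.character(disease_name) || !nzchar(trimws(disease_name))) {
    stop("disease_name must be non-empty", call. = FALSE)
  }
  mirnas <- unique(canonical_id(mirnas))
  rows <- lapply(mirnas, function(m) {
    pmids <- tryCatch(
      list(ok = TRUE, ids = unique(as.character(fetcher(m, disease_name)))),
      error = function(e) list(ok = FALSE, ids = character(0),
                               msg = conditionMessage(e))
    )
    data.frame(mirna_id = m, n_hits = length(pmids$ids),
               status = if (pmids$ok) "ok" else pmids$msg,
               stringsAsFactors = FALSE, row.names = NULL) |>
      transform(pubmed_ids = I(list(pmids$ids)))
  })
  out <- do.call(rbind, rows)
  out <- out[, c("mirna_id", "pubmed_ids", "n_hits", "status")]
  attr(out, "disease_name") <- disease_name
  attr(out, "retrieved_at") <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  attr(out, "partial") <- any(out$status != "ok")
  class(out) <- c("evidence_table", "data.frame")
  out
}

#' Live PubMed fetcher via NCBI E-utilities
#'
#' Returns a fetcher for [search_evidence()] that issues one esearch query
#' per miRNA of the form
#' `("<mirna>"[All Fields]) AND ("<disease>"[All Fields])` and returns the
#' matching PubMed ids. Requires network access; the offline test suite
#' uses stub fetchers instead. A fixed delay between requests keeps within
#' NCBI's rate limits.
#'
#' @param delay Seconds to sleep before each request (default 0.34,
#'   i.e. under 3 requests/second).
#' @param retmax Maximum ids returned per query (default 100).
#' @return A function `(mirna_id, disease_name) -> character vector`.
#' @export
pubmed_fetcher <- function(delay = 0.34, retmax = 100L) {
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi"
  function(mirna_id, disease_name) {
    Sys.sleep(delay)
    term <- sprintf('("%s"[All Fields]) AND ("%s"[All Fields])',
                    mirna_id, disease_name)
    url <- paste0(base, "?db=pubmed&retmode=json&retmax=", retmax,
                  "&term=", utils::URLencode(term, reserved = TRUE))
    res <- jsonlite::fromJSON(url)
    as.character(res$esearchresult$idlist)
  }
}

#' Write an evidence table as TSV (PubMed ids comma-joined)
#'
#' @param evidence An `evidence_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_evidence <- function(evidence, path) {
  stopifnot(inherits(evidence, "evidence_table"))
  ids <- vapply(evidence$pubmed_ids, paste, character(1), collapse = ",")
  writeLines(c(
    sprintf("# disease: %s", attr(evidence, "disease_name")),
    sprintf("# retrieved_at: %s", attr(evidence, "retrieved_at")),
    "mirna_id\tn_hits\tpubmed_ids\tstatus",
    sprintf("%s\t%d\t%s\t%s", evidence$mirna_id, evidence$n_hits, ids,
            evidence$status)
  ), path)
  invisible(path)
}
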