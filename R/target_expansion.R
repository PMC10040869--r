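#' Construct a target query
#'
#' @param uniprot_id UniProt accession of the query protein.
#' @param organism NCBI taxon restriction for the homology search
#'   (default human, `"9606"`).
#' @export
target_query <- function(uniprot_id, organism = "9606") {
  if (!is.character(uniprot_id) || length(uniprot_id) != 1 || !nzchar(uniprot_id)) {
    stop("uniprot_id must be a single non-empty string", call. = FALSE)
  }
  re <- "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"
  if (!grepl(re, uniprot_id)) {
    stop("'", uniprot_id, "' is not a valid UniProt accession", call. = FALSE)
  }
  structure(list(uniprot_id = uniprot_id, organism = organism),
            class = "lvs_target_query")
}

#' Homology-search backends
#'
#' The homology search is pluggable. `homology_backend_fixture()` serves a
#' stored table of pre-computed hits (CSV columns `query_uniprot`, `gene_name`,
#' `subject_uniprot`, `percent_identity`) and is fully offline and
#' deterministic. `homology_backend_blastp()` runs the local `blastp` binary
#' against a user-supplied subject FASTA (sequence identity as reported by
#' BLAST, maximum per subject); it requires no network but does require the
#' BLAST+ suite on PATH. A remote search service can be plugged in by
#' implementing a `search_homologs()` method.
#'
#' @param table a data frame or CSV path with the fixture schema above.
#' @return a backend object for [search_homologs()].
#' @export
homology_backend_fixture <- function(table) {
  if (is.character(table)) {
    table <- readr::read_csv(table, show_col_types = FALSE, progress = FALSE)
  }
  need <- c("query_uniprot", "gene_name", "subject_uniprot", "percent_identity")
  if (!all(need %in% names(table))) {
    stop("fixture table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  structure(list(table = tibble::as_tibble(table)),
            class = c("lvs_backend_fixture", "lvs_homology_backend"))
}

#' @rdname homology_backend_fixture
#' @param subject_fasta FASTA file of candidate protein sequences; sequence
#'   names must be `accession|gene_name` or plain accessions.
#' @param query_fasta FASTA file holding the query sequence.
#' @export
homology_backend_blastp <- function(subject_fasta, query_fasta) {
  stopifnot(file.exists(subject_fasta))
  structure(list(subject_fasta = subject_fasta, query_fasta = query_fasta),
            class = c("lvs_backend_blastp", "lvs_homology_backend"))
}

#' Search for sequence-similar proteins
#'
#' Returns every hit the backend reports for the query (restricted to the
#' backend's organism scope), unfiltered by identity. When a backend reports
#' multiple alignments for one subject accession, the maximum percent identity
#' is kept. An unknown accession yields an empty hit list with a warning.
#'
#' @param backend a homology backend.
#' @param query an [target_query()].
#' @return tibble with columns `gene_name`, `uniprot_id`, `percent_identity`.
#' @export
search_homologs <- function(backend, query) UseMethod("search_homologs")

#' @export
search_homologs.lvs_backend_fixture <- function(backend, query) {
  stopifnot(inherits(query, "lvs_target_query"))
  tab <- backend$table[backend$table$query_uniprot == query$uniprot_id, , drop = FALSE]
  if (!nrow(tab)) {
    warning("no homology hits stored for query ", query$uniprot_id, call. = FALSE)
    return(tibble::tibble(gene_name = character(0), uniprot_id = character(0),
                          percent_identity = numeric(0)))
  }
  hits <- tibble::tibble(
    gene_name = as.character(tab$gene_name),
    uniprot_id = as.character(tab$subject_uniprot),
    percent_identity = as.numeric(tab$percent_identity)
  )
  dedupe_max_identity(hits)
}

#' @export
search_homologs.lvs_backend_blastp <- function(backend, query) {
  stopifnot(inherits(query, "lvs_target_query"))
  blastp <- Sys.which("blastp")
  if (!nzchar(blastp)) stop("blastp not found on PATH", call. = FALSE)
  out <- tempfile()
  on.exit(unlink(out), add = TRUE)
  status <- system2(blastp, c("-query", shQuote(backend$query_fasta),
                              "-subject", shQuote(backend$subject_fasta),
                              "-outfmt", shQuote("6 sseqid pident"),
                              "-out", shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  lines <- if (file.exists(out)) readLines(out, warn = FALSE) else character(0)
  if (!length(lines)) {
    warning("blastp reported no hits for ", query$uniprot_id, call. = FALSE)
    return(tibble::tibble(gene_name = character(0), uniprot_id = character(0),
                          percent_identity = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sid <- vapply(parts, `[[`, "", 1L)
  pid <- as.numeric(vapply(parts, `[[`, "", 2L))
  acc_gene <- strsplit(sid, "|", fixed = TRUE)
  hits <- tibble::tibble(
    gene_name = vapply(acc_gene, function(x) if (length(x) > 1) x[[2]] else x[[1]], ""),
    uniprot_id = vapply(acc_gene, `[[`, "", 1L),
    percent_identity = pid
  )
  dedupe_max_identity(hits)
}

dedupe_max_identity <- function(hits) {
  hits |>
    dplyr::group_by(.data$uniprot_id) |>
    dplyr::slice_max(.data$percent_identity, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$percent_identity), .data$uniprot_id)
}

#' Filter homology hits to the expanded target list
#'
#' Hits with percent identity greater than or equal to the cutoff are
#' retained (the boundary is inclusive). The query itself is always part of the
#' expanded list when `include_query` is `TRUE`, whether or not the backend
#' returned a self-hit. Output is sorted by descending identity.
#'
#' @param hits tibble from [search_homologs()].
#' @param identity_cutoff percent identity threshold in (0, 100] (default 40).
#' @param include_query keep the query in the list (default `TRUE`).
#' @param query the [target_query()] (required when `include_query` is `TRUE`).
#' @export
filter_homologs <- function(hits, identity_cutoff = 40, include_query = TRUE,
                            query = NULL) {
  stopifnot(is.numeric(identity_cutoff), identity_cutoff > 0, identity_cutoff <= 100)
  keep <- hits[hits$percent_identity >= identity_cutoff, , drop = FALSE]
  if (!nrow(keep)) {
    warning("no hits passed the cutoff; downstream screening will rely on ",
            "query-only chemistry", call. = FALSE)
  }
  if (include_query) {
    if (is.null(query)) stop("include_query = TRUE requires `query`", call. = FALSE)
    if (!query$uniprot_id %in% keep$uniprot_id) {
      keep <- dplyr::bind_rows(
        tibble::tibble(gene_name = "query", uniprot_id = query$uniprot_id,
                       percent_identity = 100),
        keep
      )
    }
  }
  dplyr::arrange(keep, dplyr::desc(.data$percent_identity), .data$uniprot_id)
}
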