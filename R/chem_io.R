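#' Standardize raw SMILES into canonical structures with identity keys
#'
#' Applies the package-wide standardization policy: the largest
#' covalently-bonded fragment of the input is kept (salt / counter-ion
#' stripping; ties broken by molecular weight), canonicalized, and assigned a
#' standard InChI key. The InChI key is the compound identity used for all
#' deduplication downstream; stereochemistry is retained in the SMILES and in
#' the key. No charge neutralization or tautomer canonicalization is applied.
#'
#' @param raw_smiles character vector of SMILES strings.
#' @param source_id optional provenance identifiers (recycled names are not
#'   allowed; defaults to the input order).
#' @param on_invalid `"skip"` drops unparseable entries with a warning;
#'   `"error"` raises a parse error naming the first offending string.
#' @return A tibble with columns `smiles` (canonical), `inchikey`, `source_id`.
#'   Skipped inputs are recorded in the `"skipped"` attribute.
#' @export
standardize_molecules <- function(raw_smiles, source_id = NULL,
                                  on_invalid = c("skip", "error")) {
  on_invalid <- match.arg(on_invalid)
  if (!is.character(raw_smiles) || !length(raw_smiles)) {
    stop("raw_smiles must be a non-empty character vector", call. = FALSE)
  }
  raw_smiles <- trimws(raw_smiles)
  if (is.null(source_id)) source_id <- paste0("mol", seq_along(raw_smiles))
  source_id <- as.character(source_id)
  stopifnot(length(source_id) == length(raw_smiles))

  bad_input <- !nzchar(raw_smiles) | is.na(raw_smiles)
  # Fragment split: '.' is the SMILES component separator.
  frags <- strsplit(raw_smiles, ".", fixed = TRUE)
  frags[bad_input] <- list(character(0))
  idx <- rep(seq_along(raw_smiles), lengths(frags))
  flat <- unlist(frags, use.names = FALSE)

  chosen <- rep(NA_character_, length(raw_smiles))
  if (length(flat)) {
    d <- ob_descriptors(flat, c("atoms", "MW"))
    atoms <- suppressWarnings(as.numeric(d$atoms))
    mw <- suppressWarnings(as.numeric(d$MW))
    can <- ob_canonical(flat)
    for (i in unique(idx)) {
      j <- which(idx == i & !is.na(can) & !is.na(atoms))
      if (!length(j)) next
      best <- j[order(-atoms[j], -mw[j])][1]
      chosen[i] <- can[best]
    }
  }

  ok <- !is.na(chosen)
  if (!any(ok)) {
    if (on_invalid == "error" || length(raw_smiles) == 1) {
      offending <- raw_smiles[!ok][1]
      stop(parse_error(offending))
    }
  }
  if (any(!ok)) {
    if (on_invalid == "error") stop(parse_error(raw_smiles[!ok][1]))
    warning(sprintf("%d of %d SMILES could not be parsed and were skipped",
                    sum(!ok), length(raw_smiles)), call. = FALSE)
  }

  keys <- rep(NA_character_, length(raw_smiles))
  if (any(ok)) keys[ok] <- ob_inchikey(chosen[ok])
  ok <- ok & !is.na(keys)

  out <- tibble::tibble(
    smiles = chosen[ok],
    inchikey = keys[ok],
    source_id = source_id[ok]
  )
  attr(out, "skipped") <- tibble::tibble(
    raw = raw_smiles[!ok], source_id = source_id[!ok]
  )
  out
}

parse_error <- function(smiles) {
  structure(
    class = c("lvs_parse_error", "error", "condition"),
    list(message = sprintf("unparseable SMILES: '%s'", smiles),
         call = NULL, smiles = smiles)
  )
}

#' @rdname standardize_molecules
#' @description `standardize_molecule()` is the scalar form; it errors (with a
#'   condition of class `lvs_parse_error` carrying the offending string) on
#'   unparseable input.
#' @export
standardize_molecule <- function(raw_smiles, source_id = NULL) {
  stopifnot(length(raw_smiles) == 1)
  standardize_molecules(raw_smiles, source_id, on_invalid = "error")
}

new_library <- function(df, name, n_skipped = 0, n_duplicates = 0) {
  structure(df, class = c("lvs_library", class(df)),
            name = name, n_skipped = n_skipped, n_duplicates = n_duplicates)
}

#' Read a compound library from disk
#'
#' Supported formats: `.smi` (one `SMILES [id]` per line), `.csv` (columns
#' `smiles` and optional `id`; extra columns are dropped from the library but
#' ids are preserved), and `.sdf` (V2000/V3000). Every record is standardized
#' via [standardize_molecules()]; duplicates by InChI key are removed keeping
#' the first occurrence. Unreadable records are skipped with a warning.
#'
#' @param path input file.
#' @param format one of `"auto"`, `"smi"`, `"csv"`, `"sdf"`.
#' @param name library label (defaults to the file name).
#' @return An `lvs_library`: a tibble (`smiles`, `inchikey`, `source_id`) with
#'   attributes `name`, `n_skipped`, `n_duplicates`.
#' @export
read_library <- function(path, format = c("auto", "smi", "csv", "sdf"),
                         name = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     smi = "smi", csv = "csv", sdf = "sdf",
                     stop("cannot infer format from extension: ", path, call. = FALSE))
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    toks <- strsplit(lines, "[ \t]+")
    smiles <- vapply(toks, `[[`, "", 1L)
    ids <- vapply(seq_along(toks), function(i) {
      if (length(toks[[i]]) > 1) toks[[i]][[2]] else paste0("rec", i)
    }, "")
  } else if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    names(df) <- tolower(names(df))
    if (!"smiles" %in% names(df)) stop("CSV library needs a 'smiles' column", call. = FALSE)
    smiles <- as.character(df$smiles)
    ids <- if ("id" %in% names(df)) as.character(df$id) else paste0("rec", seq_along(smiles))
  } else {
    # SDF -> SMILES through OpenBabel; record titles kept when present.
    outfile <- tempfile(fileext = ".smi")
    on.exit(unlink(outfile), add = TRUE)
    suppressWarnings(system2(ob_binary(),
                             c("-isdf", shQuote(path), "-osmi", "-O", shQuote(outfile), "-e"),
                             stdout = FALSE, stderr = FALSE))
    lines <- if (file.exists(outfile)) readLines(outfile, warn = FALSE) else character(0)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smiles <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(seq_along(parts), function(i) {
      t <- if (length(parts[[i]]) > 1) trimws(parts[[i]][[2]]) else ""
      if (nzchar(t)) t else paste0("rec", i)
    }, "")
  }
  if (!length(smiles)) stop("no records found in ", path, call. = FALSE)

  std <- standardize_molecules(smiles, ids)
  if (!nrow(std)) stop("no valid molecules in ", path, call. = FALSE)
  n_skipped <- length(smiles) - nrow(std)
  dup <- duplicated(std$inchikey)
  n_dup <- sum(dup)
  std <- std[!dup, , drop = FALSE]
  if (n_skipped + n_dup > 0) {
    message(sprintf("read_library('%s'): %d kept, %d skipped, %d duplicates removed",
                    name, nrow(std), n_skipped, n_dup))
  }
  new_library(std, name = name, n_skipped = n_skipped, n_duplicates = n_dup)
}

#' @export
print.lvs_library <- function(x, ...) {
  cat(sprintf("<compound library '%s': %d unique molecules>\n",
              attr(x, "name"), nrow(x)))
  NextMethod()
}

#' Write a table as deterministic CSV
#'
#' UTF-8, header row, columns in the order given. Fatal on empty input or an
#' unwritable path.
#'
#' @param rows a non-empty data frame.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows) || !nrow(rows)) {
    stop("write_table: rows must be a non-empty data frame", call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("write_table: directory does not exist: ", dir, call. = FALSE)
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
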