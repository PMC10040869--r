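# Batch interface to the OpenBabel CLI.
#
# All bulk chemistry (canonicalisation, InChI keys, hashed fingerprints,
# descriptor calculation, SMARTS filtering) goes through a single `obabel`
# process per operation: the per-molecule R-level bindings are two to three
# orders of magnitude slower at screening-library scale. Molecules are tracked
# across calls by synthetic titles ("x1", "x2", ...) so that records OpenBabel
# drops (unparseable SMILES) can be mapped back to their inputs.

ob_binary <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      path <- Sys.which("obabel")
      if (!nzchar(path)) {
        stop("OpenBabel ('obabel') was not found on PATH; it is required for ",
             "all structure handling.", call. = FALSE)
      }
      cached <<- path
    }
    cached
  }
})

# Run obabel on a block of SMILES lines; returns stdout lines.
# `args` are appended verbatim (already shell-quoted where needed).
ob_run <- function(input_lines, args) {
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".txt")
  errfile <- tempfile(fileext = ".log")
  on.exit(unlink(c(infile, outfile, errfile)), add = TRUE)
  writeLines(input_lines, infile)
  status <- suppressWarnings(system2(
    ob_binary(),
    args = c(shQuote(infile), args, "-O", shQuote(outfile), "-e"),
    stdout = FALSE, stderr = errfile
  ))
  out <- if (file.exists(outfile)) readLines(outfile, warn = FALSE) else character(0)
  attr(out, "stderr") <- if (file.exists(errfile)) readLines(errfile, warn = FALSE) else character(0)
  out
}

ob_titles <- function(n) paste0("x", seq_len(n))

# Parse "smiles\ttitle[ appended fields]" lines into a data.frame aligned by title.
ob_parse_titled <- function(lines, n_fields = 0) {
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, "", 1L)
  rest <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "", "")
  toks <- strsplit(trimws(rest), "[ \t]+")
  title <- vapply(toks, function(t) if (length(t)) t[[1]] else "", "")
  out <- data.frame(title = title, smiles = smi, stringsAsFactors = FALSE)
  if (n_fields > 0) {
    fields <- vapply(toks, function(t) {
      v <- t[-1]
      length(v) <- n_fields
      v
    }, character(n_fields))
    fields <- if (n_fields == 1) matrix(fields, ncol = 1) else t(fields)
    out <- cbind(out, as.data.frame(fields, stringsAsFactors = FALSE))
  }
  out
}

# Canonical SMILES for each input; NA where OpenBabel cannot parse the input.
ob_canonical <- function(smiles) {
  n <- length(smiles)
  if (n == 0) return(character(0))
  lines <- paste(smiles, ob_titles(n))
  out <- ob_run(lines, c("-ocan"))
  parsed <- ob_parse_titled(out)
  res <- rep(NA_character_, n)
  idx <- match(parsed$title, ob_titles(n))
  ok <- !is.na(idx)
  res[idx[ok]] <- parsed$smiles[ok]
  res
}

# Named descriptor columns appended by obabel; values NA for unparseable inputs.
ob_descriptors <- function(smiles, descriptors) {
  n <- length(smiles)
  stopifnot(n > 0)
  lines <- paste(smiles, ob_titles(n))
  out <- ob_run(lines, c("-osmi", "--append", shQuote(paste(descriptors, collapse = " "))))
  parsed <- ob_parse_titled(out, n_fields = length(descriptors))
  res <- as.data.frame(matrix(NA_character_, n, length(descriptors)),
                       stringsAsFactors = FALSE)
  names(res) <- descriptors
  idx <- match(parsed$title, ob_titles(n))
  ok <- !is.na(idx)
  res[idx[ok], ] <- parsed[ok, -(1:2), drop = FALSE]
  res
}

ob_inchikey <- function(smiles) {
  d <- ob_descriptors(smiles, "InChIKey")
  d$InChIKey
}

# Hex fingerprint dump -> integer 0/1 matrix, one row per successfully parsed
# molecule, rownames = titles. OpenBabel prints 32-bit words most-significant
# first: printed word p (0-based) of W words holds bit indices
# (W-1-p)*32 .. (W-1-p)*32+31, least-significant bit first. Column j of the
# returned matrix is bit index j-1.
ob_fingerprint <- function(smiles, fp_id, n_bits = NULL) {
  n <- length(smiles)
  stopifnot(n > 0)
  lines <- paste(smiles, ob_titles(n))
  args <- c("-ofpt", paste0("-xf", fp_id), "-xh")
  if (!is.null(n_bits)) args <- c(args, "-xN", n_bits)
  out <- ob_run(lines, args)
  rec_starts <- grep("^>", out)
  if (!length(rec_starts)) stop("fingerprint generation produced no output", call. = FALSE)
  titles <- sub("^>\\s*(\\S+).*$", "\\1", out[rec_starts])
  ends <- c(rec_starts[-1] - 1L, length(out))
  hex_re <- "^[0-9a-f]{8}$"
  rows <- lapply(seq_along(rec_starts), function(i) {
    block <- out[(rec_starts[i] + 1L):ends[i]]
    words <- unlist(strsplit(trimws(block), "[ \t]+"))
    words[grepl(hex_re, words)]
  })
  wlens <- lengths(rows)
  if (length(unique(wlens[wlens > 0])) > 1) {
    stop("inconsistent fingerprint lengths in obabel output", call. = FALSE)
  }
  W <- max(wlens)
  bits <- t(vapply(rows, hex_words_to_bits, integer(W * 32L), n_words = W))
  rownames(bits) <- titles
  bits
}

# Decode a vector of 8-hex-digit words into a 0/1 integer vector (bit order above).
hex_words_to_bits <- function(words, n_words = length(words)) {
  res <- integer(n_words * 32L)
  if (!length(words)) return(res)
  hi <- strtoi(substr(words, 1, 4), 16L)
  lo <- strtoi(substr(words, 5, 8), 16L)
  pow <- 2^(0:15)
  for (p in seq_along(words)) {
    base <- (n_words - p) * 32L
    if (lo[p] > 0) res[base + which(bitwAnd(lo[p], pow) > 0)] <- 1L
    if (hi[p] > 0) res[base + 16L + which(bitwAnd(hi[p], pow) > 0)] <- 1L
  }
  res
}

# Titles of molecules matching a SMARTS pattern.
ob_smarts_match <- function(smiles, smarts) {
  n <- length(smiles)
  if (n == 0) return(character(0))
  lines <- paste(smiles, ob_titles(n))
  out <- ob_run(lines, c("-osmi", shQuote(paste0("-s", smarts))))
  parsed <- ob_parse_titled(out)
  structure(parsed$title, stderr = attr(out, "stderr"))
}
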