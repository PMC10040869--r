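#' Fingerprint specification
#'
#' Four fingerprint families are supported, mirroring the standard chemistry
#' toolkit implementations: `morgan` (extended-connectivity / circular, hashed,
#' radius 2 by default), `atompair` (hashed atom-pair descriptors), `torsion`
#' (topological torsion: linear paths of four bonded heavy atoms, each typed by
#' element, heavy-atom branching, and pi-electron count), and `maccs` (the 166
#' MDL substructure keys; fixed length). Hashed kinds fold into `n_bits`
#' (default 1024, must be a power of two); MACCS ignores `n_bits` and is always
#' 166 keys long, key k stored in column k.
#'
#' @param kind one of `"morgan"`, `"atompair"`, `"torsion"`, `"maccs"`.
#' @param radius Morgan radius (default 2; supported 0--5).
#' @param n_bits vector length for the hashed kinds (default 1024).
#' @export
fingerprint_spec <- function(kind = c("morgan", "atompair", "torsion", "maccs"),
                             radius = 2, n_bits = 1024) {
  kind <- match.arg(kind)
  stopifnot(n_bits > 0, radius >= 0)
  if (kind == "maccs") {
    n_bits <- 166L
  } else if (bitwAnd(n_bits, n_bits - 1L) != 0) {
    stop("n_bits must be a power of two for hashed fingerprints", call. = FALSE)
  }
  if (kind == "morgan" && !radius %in% 0:5) {
    stop("morgan radius must be in 0..5", call. = FALSE)
  }
  structure(list(kind = kind, radius = as.integer(radius), n_bits = as.integer(n_bits)),
            class = "lvs_fp_spec")
}

#' @export
format.lvs_fp_spec <- function(x, ...) {
  if (x$kind == "morgan") sprintf("morgan(radius=%d)/%d", x$radius, x$n_bits)
  else sprintf("%s/%d", x$kind, x$n_bits)
}

#' @export
print.lvs_fp_spec <- function(x, ...) cat("<fingerprint spec:", format(x), ">\n")

new_fpmat <- function(bits, keys, spec) {
  storage.mode(bits) <- "integer"
  rownames(bits) <- keys
  colnames(bits) <- paste0("bit", seq_len(ncol(bits)))
  structure(list(bits = bits, keys = keys, spec = spec), class = "lvs_fpmat")
}

#' @export
print.lvs_fpmat <- function(x, ...) {
  cat(sprintf("<fingerprint matrix: %d x %d, %s>\n",
              nrow(x$bits), ncol(x$bits), format(x$spec)))
}

#' Compute fingerprints for a compound set
#'
#' One row per compound in input order; compounds whose fingerprint cannot be
#' computed are skipped with a warning and excluded from the keys. The same
#' molecule gives the identical vector regardless of its SMILES notation.
#'
#' @param x an `lvs_library`, labeled compound tibble, or any data frame with
#'   `smiles` and `inchikey` columns.
#' @param spec a [fingerprint_spec()].
#' @return an `lvs_fpmat`: list with `bits` (0/1 integer matrix), `keys`
#'   (InChI keys, row order), `spec`.
#' @export
compute_fingerprints <- function(x, spec = fingerprint_spec()) {
  stopifnot(inherits(spec, "lvs_fp_spec"))
  if (!is.data.frame(x) || !all(c("smiles", "inchikey") %in% names(x))) {
    stop("x must be a data frame with 'smiles' and 'inchikey' columns", call. = FALSE)
  }
  if (!nrow(x)) stop("cannot fingerprint an empty compound set", call. = FALSE)
  smiles <- x$smiles
  keys <- x$inchikey

  bits <- switch(
    spec$kind,
    morgan = fp_hashed_ob(smiles, paste0("ECFP", 2L * spec$radius), spec$n_bits),
    maccs = fp_maccs_ob(smiles),
    atompair = fp_atompair(smiles, spec$n_bits),
    torsion = fp_torsion(smiles, spec$n_bits)
  )
  ok <- attr(bits, "ok")
  if (!any(ok)) stop("fingerprinting failed for every compound", call. = FALSE)
  if (any(!ok)) {
    warning(sum(!ok), " compound(s) could not be fingerprinted and were skipped",
            call. = FALSE)
  }
  new_fpmat(bits[ok, , drop = FALSE], keys[ok], spec)
}

# --- OpenBabel-hashed kinds ---------------------------------------------------

fp_hashed_ob <- function(smiles, fp_id, n_bits) {
  raw <- ob_fingerprint(smiles, fp_id, n_bits)
  align_fp_rows(raw, length(smiles), n_bits)
}

# OpenBabel emits MACCS as a 256-bit vector with key k at bit index k - 1
# (verified against the reference 166-key assignments); keep keys 1..166,
# key k in column k.
fp_maccs_ob <- function(smiles) {
  raw <- ob_fingerprint(smiles, "MACCS", n_bits = NULL)
  full <- align_fp_rows(raw, length(smiles), ncol(raw))
  out <- full[, 1:166, drop = FALSE]
  attr(out, "ok") <- attr(full, "ok")
  out
}

align_fp_rows <- function(raw, n, n_bits) {
  res <- matrix(0L, n, n_bits)
  idx <- match(rownames(raw), ob_titles(n))
  ok_rows <- !is.na(idx)
  res[idx[ok_rows], ] <- raw[ok_rows, seq_len(n_bits), drop = FALSE]
  ok <- logical(n)
  ok[idx[ok_rows]] <- TRUE
  attr(res, "ok") <- ok
  res
}

# --- Atom pair (ChemmineR descriptors folded by modulo) -----------------------

fp_atompair <- function(smiles, n_bits) {
  n <- length(smiles)
  res <- matrix(0L, n, n_bits)
  ok <- logical(n)
  sdf <- quiet_smiles2sdf(smiles)
  valid <- attr(sdf, "valid")
  if (any(valid)) {
    apset <- suppressWarnings(ChemmineR::sdf2ap(sdf$set))
    descs <- ChemmineR::ap(apset)
    for (j in seq_along(descs)) {
      i <- which(valid)[j]
      codes <- descs[[j]]
      ok[i] <- TRUE
      if (length(codes) && !identical(codes, 0)) {
        # ChemmineR disambiguates repeated identical pairs in the low 2^20
        # field; drop it so bits encode pair types, then fold
        types <- unique(codes %/% 2^20)
        res[i, (types %% n_bits) + 1L] <- 1L
      }
    }
  }
  attr(res, "ok") <- ok
  res
}

quiet_smiles2sdf <- function(smiles) {
  can <- ob_canonical(smiles)
  valid <- !is.na(can)
  set <- NULL
  if (any(valid)) {
    nm <- paste0("x", which(valid))
    s <- can[valid]
    names(s) <- nm
    set <- suppressWarnings(ChemmineR::smiles2sdf(s))
  }
  structure(list(set = set), valid = valid)
}

# --- Topological torsion (implemented from the molecular graph) ---------------
#
# No installed toolkit exposes topological torsion fingerprints, so paths are
# enumerated here directly. Each path of four consecutively bonded heavy atoms
# is typed per atom as (element, number of attached heavy-atom branches beyond
# the path, number of pi electrons); the path and its reverse are canonicalized
# to the lexicographically smaller orientation and hashed into n_bits.

fp_torsion <- function(smiles, n_bits) {
  n <- length(smiles)
  res <- matrix(0L, n, n_bits)
  ok <- logical(n)
  sdf <- quiet_smiles2sdf(smiles)
  valid <- attr(sdf, "valid")
  if (any(valid)) {
    for (j in seq_along(which(valid))) {
      i <- which(valid)[j]
      mol <- sdf$set[[j]]
      codes <- tryCatch(torsion_codes(mol), error = function(e) NULL)
      if (is.null(codes)) next
      ok[i] <- TRUE
      if (length(codes)) res[i, (codes %% n_bits) + 1L] <- 1L
    }
  }
  attr(res, "ok") <- ok
  res
}

torsion_codes <- function(sdf_mol) {
  ab <- ChemmineR::atomblock(sdf_mol)
  bb <- ChemmineR::bondblock(sdf_mol)
  elems <- gsub("_.*$", "", rownames(ab))
  heavy <- which(elems != "H")
  if (length(heavy) < 4 || is.null(bb) || nrow(bb) == 0) return(integer(0))
  remap <- match(seq_along(elems), heavy)

  a1 <- remap[bb[, 1]]; a2 <- remap[bb[, 2]]; ord <- bb[, 3]
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- a1[keep]; a2 <- a2[keep]; ord <- ord[keep]
  nh <- length(heavy)
  adj <- vector("list", nh)
  npi <- numeric(nh)
  for (k in seq_along(a1)) {
    adj[[a1[k]]] <- c(adj[[a1[k]]], a2[k])
    adj[[a2[k]]] <- c(adj[[a2[k]]], a1[k])
    extra <- max(ord[k] - 1, 0)
    npi[a1[k]] <- npi[a1[k]] + extra
    npi[a2[k]] <- npi[a2[k]] + extra
  }
  deg <- lengths(adj)
  elem_code <- match(elems[heavy], c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B"))
  elem_code[is.na(elem_code)] <- 11L

  # atom type at a path position: element, pi electrons, branches beyond the
  # path (ends have one path neighbour, middle atoms two)
  atom_type <- function(a, n_path_nb) {
    branches <- max(deg[a] - n_path_nb, 0)
    elem_code[a] * 64L + min(npi[a], 3) * 16L + min(branches, 15)
  }

  codes <- integer(0)
  seen <- character(0)
  for (b in seq_len(nh)) {
    for (cc in adj[[b]]) {
      if (cc <= b) next # each central bond once
      for (a in adj[[b]]) {
        if (a == cc) next
        for (d in adj[[cc]]) {
          if (d == b || d == a) next
          t <- c(atom_type(a, 1L), atom_type(b, 2L), atom_type(cc, 2L), atom_type(d, 1L))
          r <- rev(t)
          canon <- if (paste(t, collapse = ",") <= paste(r, collapse = ",")) t else r
          key <- paste(canon, collapse = ",")
          if (!key %in% seen) {
            seen <- c(seen, key)
            codes <- c(codes, torsion_hash(canon))
          }
        }
      }
    }
  }
  codes
}

# deterministic polynomial hash of the 4 type codes
torsion_hash <- function(types) {
  h <- 0
  for (t in types) h <- (h * 1000003 + t) %% 2147483647
  as.integer(h)
}

# --- Tanimoto -----------------------------------------------------------------

#' Tanimoto coefficient between bit vectors
#'
#' `Tc(a, b) = |a AND b| / |a OR b|`. If both vectors are all-zero the
#' coefficient is defined as 0.
#'
#' @param a,b binary vectors of equal length, or `b` a matrix with vectors in
#'   rows (returns one coefficient per row).
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(a != 0)
  if (is.matrix(b)) {
    inter <- as.vector(b %*% a)
    uni <- rowSums(b != 0) + sum(a) - inter
    ifelse(uni == 0, 0, inter / uni)
  } else {
    b <- as.integer(b != 0)
    inter <- sum(a & b)
    uni <- sum(a | b)
    if (uni == 0) 0 else inter / uni
  }
}

# --- serialization ------------------------------------------------------------

#' Write / read a fingerprint matrix as CSV
#'
#' The CSV has an `inchikey` column followed by one column per bit; the
#' round-trip is lossless. The spec is stored in a JSON sidecar.
#'
#' @param fpmat an `lvs_fpmat`.
#' @param path output CSV path.
#' @export
write_fingerprints <- function(fpmat, path) {
  df <- tibble::as_tibble(as.data.frame(fpmat$bits))
  names(df) <- paste0("bit", seq_len(ncol(fpmat$bits)))
  df <- dplyr::bind_cols(tibble::tibble(inchikey = fpmat$keys), df)
  write_table(df, path)
  jsonlite::write_json(unclass(fpmat$spec), paste0(path, ".spec.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  sp <- jsonlite::read_json(paste0(path, ".spec.json"), simplifyVector = TRUE)
  spec <- fingerprint_spec(sp$kind, radius = sp$radius, n_bits = sp$n_bits)
  new_fpmat(as.matrix(df[, -1]), df$inchikey, spec)
}
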