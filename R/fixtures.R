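# Synthetic structure-activity fixtures.
#
# The generator emulates the setting the pipeline is built for: a small
# homology family of pseudo-targets whose active ligands share a recognizable
# chemotype (an aryl sulfonamide by default) with potent concentration-scale
# activity, inactives and library decoys built from unrelated amide / ether /
# aniline chemotypes, and a screening library in which a known fraction of
# compounds carries the planted motif. Compounds are assembled by seeded
# combinatorial attachment of decoration fragments to scaffold templates, so
# every structure is chemically valid by construction and the planted
# substructure is controllable exactly.

#' Fixture specification
#'
#' Defaults define the package's reference study conditions: 5 pseudo-targets
#' (identities 100/85/70/55/45 percent, all above the 40 percent expansion
#' cutoff), 40 actives and 80 inactives per target (a 1:2 imbalance so
#' undersampling is exercised), lognormal potencies with medians of 100 nM
#' (actives) and 30 uM (inactives) straddling the 1000 nM cutoff by more than
#' an order of magnitude on each side, a 5000-compound screening library with
#' 5 percent planted-motif compounds, and the benzenesulfonamide planted
#' substructure.
#'
#' @param n_targets number of pseudo-targets (query + homologs).
#' @param identities percent identity per target (first = query self-hit).
#' @param n_actives_per_target,n_inactives_per_target record counts per target.
#' @param planted_smarts SMARTS of the planted active motif.
#' @param active_potency,inactive_potency `c(median, sigma)` of the lognormal
#'   potency draw, in nM.
#' @param library_size screening-library size.
#' @param library_planted_fraction fraction of library compounds carrying the
#'   motif.
#' @param seed generator seed; fixtures are byte-identical given the spec.
#' @export
fixture_spec <- function(n_targets = 5,
                         identities = c(100, 85, 70, 55, 45),
                         n_actives_per_target = 40,
                         n_inactives_per_target = 80,
                         planted_smarts = "c1ccccc1S(=O)(=O)N",
                         active_potency = c(median = 100, sigma = 1),
                         inactive_potency = c(median = 30000, sigma = 1),
                         library_size = 5000,
                         library_planted_fraction = 0.05,
                         seed = 20260101) {
  stopifnot(n_targets >= 1, length(identities) == n_targets,
            n_actives_per_target > 0, n_inactives_per_target > 0,
            library_size > 0,
            library_planted_fraction >= 0, library_planted_fraction <= 1,
            active_potency[[1]] < inactive_potency[[1]])
  structure(list(n_targets = n_targets, identities = identities,
                 n_actives_per_target = n_actives_per_target,
                 n_inactives_per_target = n_inactives_per_target,
                 planted_smarts = planted_smarts,
                 active_potency = active_potency,
                 inactive_potency = inactive_potency,
                 library_size = library_size,
                 library_planted_fraction = library_planted_fraction,
                 seed = seed),
            class = "lvs_fixture_spec")
}

# decoration fragments; written so that any template slot stays valent-legal
FIX_R1 <- c("", "C", "CC", "CCC", "C(C)C", "CCO", "CCN(C)C", "CC(C)C",
            "CCCC", "CCOC", "1CCCC1", "1CCCCC1")
FIX_R2 <- c("C", "CC", "CCC", "F", "Cl", "Br", "OC", "OCC", "C(C)C", "C#N",
            "N(C)C", "CO", "CCO", "C(F)(F)F", "N", "NC", "OC(C)C", "CCCC")
FIX_R3 <- c("", "F", "Cl", "C", "OC", "N")

# active chemotype: aryl sulfonamides
FIX_ACTIVE_TEMPLATES <- c(
  "O=S(=O)(N%1$s)c1ccc(%2$s)cc1%3$s",
  "O=S(=O)(N%1$s)c1cccc(%2$s)c1%3$s",
  "O=S(=O)(N%1$s)c1ccc(%2$s)c(%3$s)c1"
)
# decoy chemotypes: no sulfonamide anywhere
FIX_DECOY_TEMPLATES <- c(
  "O=C(N%1$s)c1ccc(%2$s)cc1%3$s",
  "O=C(N%1$s)c1cccc(%2$s)c1%3$s",
  "O=C(N%1$s)c1ccc(%2$s)c(%3$s)c1",
  "%1$sOc1ccc(%2$s)cc1%3$s",
  "%1$sNc1ccc(%2$s)cc1%3$s",
  "O=C(N%1$s)c1ccnc(%2$s)c1%3$s",
  "O=C(N%1$s)Cc1ccc(%2$s)cc1%3$s",
  "%1$sOC(=O)c1ccc(%2$s)cc1%3$s"
)

# enumerate template x R1 x R2 x R3, canonicalize, drop failures, dedupe
enumerate_pool <- function(templates, r3 = FIX_R3) {
  combos <- expand.grid(t = templates, r1 = FIX_R1, r2 = FIX_R2, r3 = r3,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  # empty third slot only valid at a terminal ring position for %3$s-suffix
  # templates; sprintf handles "" naturally there
  smi <- sprintf(combos$t, combos$r1, combos$r2, combos$r3)
  can <- ob_canonical(smi)
  ok <- !is.na(can)
  keys <- rep(NA_character_, length(can))
  keys[ok] <- ob_inchikey(can[ok])
  ok <- ok & !is.na(keys) & !duplicated(keys)
  tibble::tibble(smiles = can[ok], inchikey = keys[ok])
}

#' Check a molecule for the planted substructure
#'
#' @param smiles SMILES string(s).
#' @param smarts SMARTS pattern (default: the default planted motif).
#' @return logical vector: pattern present.
#' @export
plant_check <- function(smiles, smarts = fixture_spec()$planted_smarts) {
  validate_smarts(smarts)
  hits <- ob_smarts_match(smiles, smarts)
  seq_along(smiles) %in% match(hits, ob_titles(length(smiles)))
}

# a pattern OpenBabel cannot parse is a configuration error, not "no match"
validate_smarts <- function(smarts) {
  err <- attr(ob_smarts_match("C", smarts), "stderr")
  if (any(grepl("SMARTS", err, ignore.case = TRUE) & grepl("error|invalid", err,
                                                           ignore.case = TRUE))) {
    stop("invalid SMARTS pattern: '", smarts, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate the offline fixture set
#'
#' Writes three files to `dir`: `homology.csv` (fixture backend schema),
#' `bioactivity.csv` (activity-record schema), and `library.smi` (screening
#' library). All randomness derives from the spec seed; the same spec yields
#' byte-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the three file paths and the generated
#'   tables (`homology`, `bioactivity`, `library`).
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "lvs_fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  actives_pool <- enumerate_pool(FIX_ACTIVE_TEMPLATES)
  decoys_pool <- enumerate_pool(FIX_DECOY_TEMPLATES)
  # construction guarantee: actives all carry the motif, decoys never do
  decoys_pool <- decoys_pool[!plant_check(decoys_pool$smiles, spec$planted_smarts), ]

  n_act_total <- spec$n_targets * spec$n_actives_per_target
  n_inact_total <- spec$n_targets * spec$n_inactives_per_target
  n_lib_planted <- round(spec$library_size * spec$library_planted_fraction)
  n_lib_decoys <- spec$library_size - n_lib_planted
  if (nrow(actives_pool) < n_act_total + n_lib_planted) {
    stop(sprintf("fixture spec needs %d unique planted-motif structures; only %d could be enumerated",
                 n_act_total + n_lib_planted, nrow(actives_pool)), call. = FALSE)
  }
  if (nrow(decoys_pool) < n_inact_total + n_lib_decoys) {
    stop(sprintf("fixture spec needs %d unique decoy structures; only %d could be enumerated",
                 n_inact_total + n_lib_decoys, nrow(decoys_pool)), call. = FALSE)
  }

  act_idx <- sample(nrow(actives_pool), n_act_total + n_lib_planted)
  dec_idx <- sample(nrow(decoys_pool), n_inact_total + n_lib_decoys)
  train_act <- actives_pool[act_idx[seq_len(n_act_total)], ]
  lib_act <- actives_pool[act_idx[n_act_total + seq_len(n_lib_planted)], ]
  train_dec <- decoys_pool[dec_idx[seq_len(n_inact_total)], ]
  lib_dec <- decoys_pool[dec_idx[n_inact_total + seq_len(n_lib_decoys)], ]

  targets <- sprintf("P1%04d", seq_len(spec$n_targets))
  homology <- tibble::tibble(
    query_uniprot = targets[1],
    gene_name = sprintf("GENE%d", seq_len(spec$n_targets)),
    subject_uniprot = targets,
    percent_identity = spec$identities
  )

  draw_potency <- function(n, p) stats::rlnorm(n, log(p[[1]]), p[[2]])
  mixed_units <- function(v) {
    um <- stats::runif(length(v)) < 0.2
    tibble::tibble(standard_value = ifelse(um, v / 1000, v),
                   standard_units = ifelse(um, "uM", "nM"))
  }
  rows <- list()
  for (t in seq_along(targets)) {
    a <- train_act[(t - 1) * spec$n_actives_per_target + seq_len(spec$n_actives_per_target), ]
    i <- train_dec[(t - 1) * spec$n_inactives_per_target + seq_len(spec$n_inactives_per_target), ]
    av <- mixed_units(draw_potency(nrow(a), spec$active_potency))
    iv <- mixed_units(draw_potency(nrow(i), spec$inactive_potency))
    rows[[t]] <- dplyr::bind_rows(
      dplyr::bind_cols(a, av, tibble::tibble(target_uniprot = targets[t],
                                             value_type = "IC50")),
      dplyr::bind_cols(i, iv, tibble::tibble(target_uniprot = targets[t],
                                             value_type = "IC50"))
    )
    # a sprinkling of binding-assay records for the datatype table
    ki <- a[seq_len(min(3, nrow(a))), ]
    rows[[t]] <- dplyr::bind_rows(rows[[t]], dplyr::bind_cols(
      ki, tibble::tibble(standard_value = draw_potency(nrow(ki), spec$active_potency),
                         standard_units = "nM", target_uniprot = targets[t],
                         value_type = "Ki")))
  }
  bioactivity <- dplyr::bind_rows(rows) |>
    dplyr::select("smiles", "inchikey", "target_uniprot", "value_type",
                  "standard_value", "standard_units")

  library_tbl <- dplyr::bind_rows(lib_dec, lib_act)
  library_tbl <- library_tbl[sample(nrow(library_tbl)), ]
  library_tbl$id <- sprintf("LIB%05d", seq_len(nrow(library_tbl)))

  paths <- list(homology = file.path(dir, "homology.csv"),
                bioactivity = file.path(dir, "bioactivity.csv"),
                library = file.path(dir, "library.smi"))
  write_table(homology, paths$homology)
  write_table(bioactivity, paths$bioactivity)
  writeLines(paste(library_tbl$smiles, library_tbl$id), paths$library)
  invisible(c(paths, list(homology_tbl = homology, bioactivity_tbl = bioactivity,
                          library_tbl = library_tbl, query = targets[1],
                          spec = spec)))
}
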