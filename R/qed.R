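# Quantitative estimate of drug-likeness (QED).
#
# QED is the weighted geometric mean of eight desirability functions, each an
# asymmetric double sigmoid fitted to the property distributions of approved
# oral drugs (Bickerton et al., Nature Chemistry 2012). The published ADS
# constants and weights are embedded below. The structural ALERTS term counts
# how many patterns from a curated list of published unwanted-functionality
# substructures are present; drug-like molecules free of such motifs have
# ALERTS = 0.

# columns: a, b, c, d, e, f, dmax (published values)
QED_ADS <- matrix(c(
  2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561,   # MW
  3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604,   # ALOGP
  2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046,   # HBA
  1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616,   # HBD
  1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167,   # PSA
  0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403,   # ROTB
  3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610,   # AROM
  0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140),  # ALERTS
  nrow = 8, byrow = TRUE,
  dimnames = list(c("MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM", "ALERTS"),
                  c("a", "b", "c", "d", "e", "f", "dmax")))

QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# Curated subset of the published unwanted-functionality alerts (reactive or
# promiscuous motifs). Patterns are written in SMARTS accepted by OpenBabel.
QED_ALERT_SMARTS <- c(
  "[S,C](=[O,S])[F,Br,Cl,I]",          # acyl / sulfonyl halide
  "[CX3](=[OX1])[OX2][CX3](=[OX1])",   # anhydride
  "C(=O)N[OH]",                        # hydroxamic acid
  "[N+]([O-])=O",                      # nitro (charged form)
  "N=[N+]=[N-]",                       # azide
  "N=N",                               # azo
  "[NX2]=[OX1]",                       # nitroso
  "[SH]",                              # thiol
  "[OX2][OX2]",                        # peroxide
  "[NX3][NX3]",                        # hydrazine
  "C=[N-]",                            # isocyanide-like
  "N=C=O",                             # isocyanate
  "N=C=S",                             # isothiocyanate
  "S=C=N",                             # thiocyanate
  "[CX3](=O)[CX3](=O)",                # 1,2-diketone
  "C1OC1",                             # epoxide
  "C1NC1",                             # aziridine
  "C1SC1",                             # thiirane
  "[CH1]=O",                           # aldehyde
  "[C;!R]=[C;!R][C;!R]=[C;!R]",        # acyclic polyene
  "[Si]", "[B]", "[Se]",               # atypical heteroatoms
  "[C;!R](=O)[C;!R]=[C;!R]",           # acyclic Michael acceptor
  "O=C[F,Cl,Br,I]",                    # haloformyl
  "[#6]S(=O)(=O)O[#6]",                # sulfonate ester
  "COS(=O)(=O)[#6]",                   # sulfonyloxy leaving group
  "[I]",                               # iodine
  "[N;R0]=[N;R0]C#N",                  # azo-nitrile
  "C=C=C"                              # allene
)

# ADS desirability, vectorized over x for one property row.
qed_ads <- function(x, p) {
  v <- p["a"] + p["b"] /
    (1 + exp(-(x - p["c"] + p["d"] / 2) / p["e"])) *
    (1 - 1 / (1 + exp(-(x - p["c"] - p["d"] / 2) / p["f"])))
  pmax(v / p["dmax"], 1e-10)
}

#' QED from pre-computed property values
#'
#' @param mw molecular weight (g/mol).
#' @param logp octanol/water partition coefficient.
#' @param hba,hbd hydrogen-bond acceptor / donor counts.
#' @param tpsa topological polar surface area.
#' @param rotb rotatable bond count.
#' @param arom aromatic ring count.
#' @param alerts count of structural-alert patterns present.
#' @return QED values in \[0, 1\] (weighted geometric mean of the eight
#'   desirabilities).
#' @export
qed_score <- function(mw, logp, hba, hbd, tpsa, rotb, arom, alerts) {
  vals <- rbind(MW = mw, ALOGP = logp, HBA = hba, HBD = hbd,
                PSA = tpsa, ROTB = rotb, AROM = arom, ALERTS = alerts)
  props <- rownames(vals)
  d <- sapply(props, function(p) qed_ads(as.numeric(vals[p, ]), QED_ADS[p, ]))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1, dimnames = list(NULL, props))
  w <- QED_WEIGHTS[props]
  exp(as.vector(log(d) %*% w) / sum(w))
}
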