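#' Signaling network container
#'
#' A `signaling_network` holds the fixed reaction topology from which the
#' mass-action signaling ODE system is generated: species (each flagged as
#' `dynamic` -- carries an ODE --, `algebraic` -- computed from a conservation
#' relation --, or `input` -- a delivered ligand), signed activation/inhibition
#' edges, conservation pairs (a phosphorylated or complexed form plus its free
#' complement summing to a constant total), ligand-receptor bindings, and the
#' total concentrations.
#'
#' @param species data.frame with columns `id`, `role` (one of `"dynamic"`,
#'   `"algebraic"`, `"input"`).
#' @param edges data.frame with columns `from`, `to`, `sign`
#'   (`"activate"`/`"inhibit"`). `from` is the species whose *active* pool
#'   drives the reaction.
#' @param pairs data.frame with columns `phospho`, `base`, `total_id`: the
#'   conservation pairs `[phospho] + [base] = total`.
#' @param ligand_bindings data.frame with columns `ligand`, `receptor`,
#'   `complex`.
#' @param totals named numeric vector mapping `total_id` to a positive
#'   concentration (arbitrary units).
#' @return An object of class `signaling_network`.
#' @seealso [build_canonical_network()], [validate_network()]
#' @export
signaling_network <- function(species, edges, pairs, ligand_bindings, totals) {
  net <- structure(
    list(
      species = as.data.frame(species, stringsAsFactors = FALSE),
      edges = as.data.frame(edges, stringsAsFactors = FALSE),
      pairs = as.data.frame(pairs, stringsAsFactors = FALSE),
      ligand_bindings = as.data.frame(ligand_bindings, stringsAsFactors = FALSE),
      totals = totals
    ),
    class = "signaling_network"
  )
  net
}

#' Canonical BMP-2/IGF-1 signaling topology
#'
#' Builds the fixed signaling topology used throughout the package: the BMP-2
#' arm (receptor complex -> TAK1 -> p38 MAPK -> Runx2 and receptor complex ->
#' SMAD1/5 -> Runx2), the IGF-1 arm (receptor complex -> Ras -> c-Raf -> MEK ->
#' ERK -> proliferative program, and receptor complex -> PI3K -> PDK1 -> Akt
#' with the Akt -> GSK3beta -> beta-catenin and Akt -> mTOR -> p70S6K -> S6 /
#' osterix branches), and the ERK -| SMAD1/5 cross-talk inhibition.
#'
#' The system has exactly 20 dynamic species (one ODE each), 16 algebraic
#' species (conservation complements: 14 unphosphorylated protein pools and the
#' 2 free receptor pools), and 37 rate parameters (21 association or
#' phosphorylation rates, one per activation edge, and 16 deactivation rates:
#' per-species basal dephosphorylation/dissociation with a single shared rate
#' within each of the Raf/MEK/ERK, PI3K/PDK1/Akt and p70S6K/S6 cascades, plus
#' the ERK-mediated SMAD1/5 inhibition rate).
#'
#' Sign convention: for GSK3beta and beta-catenin the tracked state is the
#' *phosphorylated* (inactive, degradation-bound) pool; downstream activity is
#' read from the unphosphorylated complement `C_M - [pM]`. Akt phosphorylates
#' (inactivates) GSK3beta; *active* (unphosphorylated) GSK3beta phosphorylates
#' (inactivates) beta-catenin, so Akt signaling de-represses beta-catenin.
#' The four unpaired activity variables (active Ras and the Runx2, osterix and
#' proliferative transcription-factor programs) are normalized activities on
#' `[0, 1]` with an implicit unit capacity.
#'
#' @return A valid `signaling_network`; two calls return identical structures.
#' @examples
#' net <- build_canonical_network()
#' sum(net$species$role == "dynamic")  # 20
#' validate_network(net)               # character(0)
#' @export
build_canonical_network <- function() {
  dynamic <- c(
    "cBMPR", "cIGFR",
    "pTAK1", "pP38", "pSMAD15",
    "aRas", "pCRaf", "pMEK", "pERK",
    "pPI3K", "pPDK1", "pAkt",
    "pGSK3B", "pBcat",
    "pMTOR", "pP70S6K", "pS6",
    "aRunx2", "aOsterix", "aProlif"
  )
  algebraic <- c(
    "BMPR", "IGFR",
    "TAK1", "P38", "SMAD15",
    "CRaf", "MEK", "ERK",
    "PI3K", "PDK1", "Akt",
    "GSK3B", "Bcat",
    "MTOR", "P70S6K", "S6"
  )
  inputs <- c("BMP2", "IGF1")
  species <- data.frame(
    id = c(dynamic, algebraic, inputs),
    role = c(
      rep("dynamic", length(dynamic)),
      rep("algebraic", length(algebraic)),
      rep("input", length(inputs))
    ),
    stringsAsFactors = FALSE
  )

  edges <- data.frame(
    from = c(
      "BMP2", "IGF1",
      "cBMPR", "pTAK1", "cBMPR",
      "cIGFR", "aRas", "pCRaf", "pMEK",
      "cIGFR", "pPI3K", "pPDK1",
      "pAkt", "GSK3B",
      "pAkt", "pMTOR", "pP70S6K",
      "pP38", "pSMAD15", "pMTOR", "pERK",
      "pERK"
    ),
    to = c(
      "cBMPR", "cIGFR",
      "pTAK1", "pP38", "pSMAD15",
      "aRas", "pCRaf", "pMEK", "pERK",
      "pPI3K", "pPDK1", "pAkt",
      "pGSK3B", "pBcat",
      "pMTOR", "pP70S6K", "pS6",
      "aRunx2", "aRunx2", "aOsterix", "aProlif",
      "pSMAD15"
    ),
    sign = c(rep("activate", 21), "inhibit"),
    stringsAsFactors = FALSE
  )

  pairs <- data.frame(
    phospho = c("cBMPR", "cIGFR", "pTAK1", "pP38", "pSMAD15", "pCRaf", "pMEK",
                "pERK", "pPI3K", "pPDK1", "pAkt", "pGSK3B", "pBcat", "pMTOR",
                "pP70S6K", "pS6"),
    base = c("BMPR", "IGFR", "TAK1", "P38", "SMAD15", "CRaf", "MEK", "ERK",
             "PI3K", "PDK1", "Akt", "GSK3B", "Bcat", "MTOR", "P70S6K", "S6"),
    total_id = c("C_BMPR", "C_IGFR", "C_TAK1", "C_P38", "C_SMAD15", "C_CRaf",
                 "C_MEK", "C_ERK", "C_PI3K", "C_PDK1", "C_Akt", "C_GSK3B",
                 "C_Bcat", "C_MTOR", "C_P70S6K", "C_S6"),
    stringsAsFactors = FALSE
  )

  ligand_bindings <- data.frame(
    ligand = c("BMP2", "IGF1"),
    receptor = c("BMPR", "IGFR"),
    complex = c("cBMPR", "cIGFR"),
    stringsAsFactors = FALSE
  )

  totals <- rep(1, nrow(pairs))
  names(totals) <- pairs$total_id

  signaling_network(species, edges, pairs, ligand_bindings, totals)
}

#' Validate a signaling network against its structural invariants
#'
#' Checks the structural contract of the canonical model: exactly 20 dynamic
#' species, 16 algebraic species (36 variables in all), every algebraic species
#' in exactly one conservation pair, every conservation total present and
#' positive, all edge endpoints defined, and both ligands (BMP-2, IGF-1)
#' present as pure sources.
#'
#' @param net A `signaling_network`.
#' @return Character vector of human-readable violation messages; `character(0)`
#'   if all invariants hold. Violations are returned, never raised.
#' @export
validate_network <- function(net) {
  v <- character(0)
  sp <- net$species
  n_dyn <- sum(sp$role == "dynamic")
  n_alg <- sum(sp$role == "algebraic")
  if (n_dyn != 20L)
    v <- c(v, sprintf("expected 20 dynamic species (one ODE each), found %d", n_dyn))
  if (n_alg != 16L)
    v <- c(v, sprintf("expected 16 algebraic species, found %d", n_alg))
  if (n_dyn + n_alg != 36L)
    v <- c(v, sprintf("expected 36 model variables, found %d", n_dyn + n_alg))

  alg <- sp$id[sp$role == "algebraic"]
  paired <- c(net$pairs$phospho, net$pairs$base)
  for (a in alg) {
    k <- sum(net$pairs$base == a | net$pairs$phospho == a)
    if (k != 1L)
      v <- c(v, sprintf("algebraic species '%s' appears in %d conservation pairs (expected 1)", a, k))
  }
  dup <- paired[duplicated(paired)]
  for (d in unique(dup))
    v <- c(v, sprintf("species '%s' appears in more than one conservation pair", d))

  for (i in seq_len(nrow(net$pairs))) {
    tid <- net$pairs$total_id[i]
    if (!tid %in% names(net$totals)) {
      v <- c(v, sprintf("total '%s' (pair %s/%s) missing from totals", tid,
                        net$pairs$phospho[i], net$pairs$base[i]))
    } else if (!is.finite(net$totals[[tid]]) || net$totals[[tid]] <= 0) {
      v <- c(v, sprintf("total '%s' must be positive, found %s", tid,
                        format(net$totals[[tid]])))
    }
  }

  ends <- unique(c(net$edges$from, net$edges$to))
  missing <- setdiff(ends, sp$id)
  for (m in missing)
    v <- c(v, sprintf("edge endpoint '%s' is not a declared species", m))
  bad_sign <- setdiff(unique(net$edges$sign), c("activate", "inhibit"))
  for (s in bad_sign)
    v <- c(v, sprintf("edge sign '%s' is not 'activate' or 'inhibit'", s))

  for (lig in c("BMP2", "IGF1")) {
    if (!lig %in% sp$id) {
      v <- c(v, sprintf("ligand '%s' missing from species", lig))
    } else if (lig %in% net$edges$to) {
      v <- c(v, sprintf("ligand '%s' must be a pure source (has incoming edges)", lig))
    }
  }
  for (i in seq_len(nrow(net$ligand_bindings))) {
    lb <- net$ligand_bindings[i, ]
    for (col in c("ligand", "receptor", "complex"))
      if (!lb[[col]] %in% sp$id)
        v <- c(v, sprintf("ligand binding refers to unknown species '%s'", lb[[col]]))
  }
  v
}

#' @export
print.signaling_network <- function(x, ...) {
  n_dyn <- sum(x$species$role == "dynamic")
  n_alg <- sum(x$species$role == "algebraic")
  cat("Signaling network:", n_dyn, "dynamic +", n_alg, "algebraic species,",
      nrow(x$edges), "edges,", nrow(x$pairs), "conservation pairs\n")
  viol <- validate_network(x)
  if (length(viol)) {
    cat("INVALID:\n")
    for (m in viol) cat("  -", m, "\n")
  }
  invisible(x)
}

#' Read/write a signaling network as JSON
#'
#' The on-disk schema is a JSON object with keys `species`, `edges`, `pairs`,
#' `ligand_bindings` (each an array of records) and `totals` (an object mapping
#' total id to value), so topology variants can be tested without code changes.
#'
#' @param net A `signaling_network`.
#' @param path File path.
#' @return `write_network` returns `path` invisibly; `read_network` returns the
#'   parsed `signaling_network`.
#' @export
write_network <- function(net, path) {
  obj <- list(
    species = net$species,
    edges = net$edges,
    pairs = net$pairs,
    ligand_bindings = net$ligand_bindings,
    totals = as.list(net$totals)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  totals <- unlist(obj$totals)
  signaling_network(obj$species, obj$edges, obj$pairs, obj$ligand_bindings, totals)
}
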