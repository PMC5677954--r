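#' Kinetic rate parameters of the signaling system
#'
#' A named vector of the mass-action rate constants, each tagged by its name
#' prefix as an activation/association rate (`a_*`, per concentration per hour)
#' or a deactivation/dissociation rate (`d_*`). The canonical network uses
#' exactly 37 parameters.
#'
#' @param values Named numeric vector of positive rates.
#' @return Object of class `kinetic_params` (a named numeric vector).
#' @export
kinetic_params <- function(values) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("kinetic parameters must be named")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all kinetic rates must be positive and finite")
  bad <- names(values)[!grepl("^[ad]_", names(values))]
  if (length(bad))
    stop("parameter names must start with 'a_' or 'd_': ", paste(bad, collapse = ", "))
  structure(as.numeric(stats::setNames(values, names(values))),
            names = names(values), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (", length(x), " rates: ",
      sum(startsWith(names(x), "a_")), " activation, ",
      sum(startsWith(names(x), "d_")), " deactivation)\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Ground-truth kinetic parameters for the canonical network
#'
#' The packaged default rate constants (per concentration per hour) under which
#' the synthetic-data generator operates. Receptor binding is fast and tight;
#' kinase cascade steps relax on the hour scale; the transcription-factor
#' activity programs integrate more slowly; the ERK-mediated SMAD1/5
#' dephosphorylation is strong enough to curtail, but not abolish, Runx2
#' activation when IGF-1 overlaps BMP-2 signaling.
#'
#' @return A `kinetic_params` vector of length 37.
#' @export
default_kinetic_params <- function() {
  kinetic_params(c(
    # ligand-receptor association
    a_cBMPR = 1.0, a_cIGFR = 1.0,
    # BMP-2 arm
    a_pTAK1 = 0.5, a_pP38 = 0.5, a_pSMAD15 = 0.5,
    # IGF-1 / MAPK arm
    a_aRas = 0.6, a_pCRaf = 0.5, a_pMEK = 0.5, a_pERK = 0.5,
    # IGF-1 / PI3K arm
    a_pPI3K = 0.5, a_pPDK1 = 0.5, a_pAkt = 0.5,
    a_pGSK3B = 0.5, a_pBcat = 0.4,
    a_pMTOR = 0.4, a_pP70S6K = 0.5, a_pS6 = 0.5,
    # transcription-factor programs (Runx2 driven mainly through SMAD1/5,
    # with a weaker p38 arm, so the ERK cross-talk has leverage)
    a_aRunx2_pP38 = 0.04, a_aRunx2_pSMAD15 = 0.32,
    a_aOsterix = 0.2, a_aProlif = 0.3,
    # dissociation / dephosphorylation
    d_cBMPR = 0.1, d_cIGFR = 0.1,
    d_pTAK1 = 0.2, d_pP38 = 0.2, d_pSMAD15 = 0.2,
    d_aRas = 0.3, d_mapk = 0.2, d_pi3k = 0.2,
    d_pGSK3B = 0.2, d_pBcat = 0.1,
    d_pMTOR = 0.2, d_s6k = 0.2,
    d_aRunx2 = 0.15, d_aOsterix = 0.08, d_aProlif = 0.1,
    # cross-talk: ERK-mediated SMAD1/5 inactivation
    d_pSMAD15_pERK = 5
  ))
}

# Rate-law term table for a network: one row per mass-action term. Activation
# edges map to a_<target> (disambiguated by source when a species has several
# activators); basal deactivation maps to a per-species d parameter with the
# canonical shared rates within the Raf/MEK/ERK, PI3K/PDK1/Akt and p70S6K/S6
# cascades; inhibition edges map to d_<target>_<source>.
param_table <- function(net) {
  dyn <- net$species$id[net$species$role == "dynamic"]
  shares <- list(
    d_mapk = c("pCRaf", "pMEK", "pERK"),
    d_pi3k = c("pPI3K", "pPDK1", "pAkt"),
    d_s6k = c("pP70S6K", "pS6")
  )
  d_param_for <- function(sp) {
    for (nm in names(shares)) if (sp %in% shares[[nm]]) return(nm)
    paste0("d_", sp)
  }
  cap_for <- function(sp) {
    i <- match(sp, net$pairs$phospho)
    if (is.na(i)) NA_character_ else net$pairs$total_id[i]
  }
  rows <- list()
  act <- net$edges[net$edges$sign == "activate" & net$edges$to %in% dyn, , drop = FALSE]
  multi <- names(which(table(act$to) > 1))
  for (i in seq_len(nrow(act))) {
    tgt <- act$to[i]; src <- act$from[i]
    pid <- if (tgt %in% multi) paste0("a_", tgt, "_", src) else paste0("a_", tgt)
    rows[[length(rows) + 1L]] <- data.frame(
      param = pid, type = "a", target = tgt, source = src,
      capacity = cap_for(tgt), stringsAsFactors = FALSE)
  }
  for (tgt in dyn) {
    rows[[length(rows) + 1L]] <- data.frame(
      param = d_param_for(tgt), type = "d", target = tgt, source = NA_character_,
      capacity = cap_for(tgt), stringsAsFactors = FALSE)
  }
  inh <- net$edges[net$edges$sign == "inhibit" & net$edges$to %in% dyn, , drop = FALSE]
  for (i in seq_len(nrow(inh))) {
    tgt <- inh$to[i]; src <- inh$from[i]
    rows[[length(rows) + 1L]] <- data.frame(
      param = paste0("d_", tgt, "_", src), type = "d", target = tgt,
      source = src, capacity = cap_for(tgt), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
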