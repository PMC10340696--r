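# SE-HPLC protein-fraction summaries: absorbance-area percentages per
# fraction set and the composition ratios Gli:Glu, HMW:LMW, UPP:TPP.
# Fractions: F1 = HMW polymeric (glutenin), F2 = LMW glutenin polymers,
# F3 = gliadins, F4 = albumins/globulins/hydrolysates; E = SDS-extractable,
# U = SDS-unextractable, T = E + U.

.fraction_cols <- function(areas, set, fracs = 1:4) {
  cols <- paste0(set, "_F", fracs)
  present <- cols[cols %in% names(areas)]
  as.matrix(areas[present])
}

#' Absorbance-area percentages per fraction
#'
#' A% of fraction k within a set is 100 * AA_k / sum(AA) over the fractions
#' present in that set; the total (T) set uses the E + U sum per fraction.
#' A% is scale-free: it reflects protein composition rather than total
#' protein content.
#'
#' @param areas Fraction-area data frame (see [read_fraction_areas()]).
#' @return Data frame: `sample` plus `<set>_F<k>_pct` columns for each set
#'   (E, U, T) and fraction present. Rows of a set sum to 100.
#' @export
area_percent <- function(areas) {
  out <- data.frame(sample = areas$sample, stringsAsFactors = FALSE)
  for (set in c("E", "U")) {
    m <- .fraction_cols(areas, set)
    if (!ncol(m)) next
    tot <- rowSums(m)
    if (any(!is.finite(tot) | tot <= 0))
      stop("zero or invalid total absorbance area in set ", set,
           call. = FALSE)
    pct <- 100 * m / tot
    colnames(pct) <- paste0(colnames(m), "_pct")
    out <- cbind(out, pct)
  }
  e <- .fraction_cols(areas, "E")
  u <- .fraction_cols(areas, "U")
  shared <- intersect(sub("^E", "", colnames(e)), sub("^U", "", colnames(u)))
  if (length(shared)) {
    tm <- e[, paste0("E", shared), drop = FALSE] +
      u[, paste0("U", shared), drop = FALSE]
    tot <- rowSums(tm)
    if (any(!is.finite(tot) | tot <= 0))
      stop("zero or invalid total absorbance area in set T", call. = FALSE)
    pct <- 100 * tm / tot
    colnames(pct) <- paste0("T", shared, "_pct")
    out <- cbind(out, pct)
  }
  out
}

#' Protein-composition ratios from raw absorbance areas
#'
#' Per sample:
#' * Gli:Glu = F3 / (F1 + F2), the gliadin to glutenin ratio, on the total
#'   (E + U) fractions by default or the extractable set only;
#' * HMW:LMW = F1 / F2 for each of the E, U and T sets;
#' * UPP:TPP = U(F1 + F2) / (E(F1 + F2) + U(F1 + F2)), the SDS-unextractable
#'   share of the polymeric protein, always in `[0, 1]`.
#'
#' F4 (albumins/globulins) enters none of the ratios. A zero denominator
#' yields `NA` and the sample is listed in the `flagged` attribute.
#'
#' @param areas Fraction-area data frame.
#' @param gliadin_set `"total"` (default) or `"extractable"`: fraction set
#'   used for the Gli:Glu ratio.
#' @return Data frame with columns `sample`, `Gli_Glu`, `HMW_LMW_E`,
#'   `HMW_LMW_U`, `HMW_LMW_T`, `UPP_TPP`.
#' @export
fraction_ratios <- function(areas, gliadin_set = c("total", "extractable")) {
  gliadin_set <- match.arg(gliadin_set)
  e <- .fraction_cols(areas, "E", 1:3)
  u <- .fraction_cols(areas, "U", 1:3)
  t3 <- e + u
  colnames(t3) <- sub("^E", "T", colnames(e))
  div <- function(num, den) ifelse(den > 0, num / den, NA_real_)

  gsrc <- if (gliadin_set == "total") t3 else e
  gcol <- function(m, k) m[, grep(paste0("F", k, "$"), colnames(m))]
  out <- data.frame(
    sample = areas$sample,
    Gli_Glu = div(gcol(gsrc, 3), gcol(gsrc, 1) + gcol(gsrc, 2)),
    HMW_LMW_E = div(gcol(e, 1), gcol(e, 2)),
    HMW_LMW_U = div(gcol(u, 1), gcol(u, 2)),
    HMW_LMW_T = div(gcol(t3, 1), gcol(t3, 2)),
    UPP_TPP = div(gcol(u, 1) + gcol(u, 2),
                  gcol(e, 1) + gcol(e, 2) + gcol(u, 1) + gcol(u, 2)),
    stringsAsFactors = FALSE)
  flagged <- out$sample[rowSums(is.na(out[-1])) > 0]
  attr(out, "flagged") <- flagged
  out
}

#' Protein-composition traits in reporting layout
#'
#' Binds the total-set area percentages of F1-F3 (reported as T_HMW, T_LMW,
#' T_Gli, in A%) with the T-set HMW:LMW, the Gli:Glu and the UPP:TPP ratios,
#' using the column names conventional in quality-trial reports.
#'
#' @inheritParams fraction_ratios
#' @return Data frame: sample, T_HMW, T_LMW, T_Gli, T_HMW:LMW, T_Gli:Glu,
#'   UPP:TPP.
#' @export
fraction_trait_table <- function(areas, gliadin_set = "total") {
  pct <- area_percent(areas)
  rat <- fraction_ratios(areas, gliadin_set = gliadin_set)
  out <- data.frame(sample = areas$sample,
                    T_HMW = pct$T_F1_pct, T_LMW = pct$T_F2_pct,
                    T_Gli = pct$T_F3_pct,
                    rat$HMW_LMW_T, rat$Gli_Glu, rat$UPP_TPP,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[5:7] <- c("T_HMW:LMW", "T_Gli:Glu", "UPP:TPP")
  out
}
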