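#' Staining sensitivity
#'
#' The proportion of reference-identified cells, down to `depth_max` into
#' the gel, whose HCR signal-to-background ratio meets the detection rule
#' (ratio >= 20 by default). With well-permeabilized cells this approaches
#' 1; with depth-limited permeabilization it falls toward the mean staining
#' efficiency over the depth window.
#'
#' @param records Stain-record data.frame (`depth`, `hcr_signal`,
#'   `background`, `ref_detected`).
#' @param ratio_threshold Detection S/B threshold (default 20).
#' @param depth_max Depth window, um (default 600).
#' @return Fraction in `[0, 1]`.
#' @export
sensitivity <- function(records, ratio_threshold = 20, depth_max = 600) {
  elig <- records$depth <= depth_max & records$ref_detected
  if (!any(elig)) stop("no eligible cells (depth <= depth_max and reference-detected)")
  r <- records$hcr_signal[elig] / records$background[elig]
  mean(r >= ratio_threshold)
}

#' Empirical CDF of signal-to-background ratios
#'
#' Right-continuous step ECDF over S/B ratios of stain records or segmented
#' objects, evaluable at arbitrary points (the curve reported for staining
#' benchmarks, with the detection threshold drawn as a vertical rule).
#'
#' @param x Either a stain-record data.frame (`hcr_signal`, `background`),
#'   a numeric vector of ratios, or a segmented-object data.frame with
#'   `mean_intensity` plus `background_level`.
#' @param background_level Background scalar when `x` carries raw
#'   intensities.
#' @return A function of class `ecdf`.
#' @export
ratio_ecdf <- function(x, background_level = NULL) {
  r <- if (is.numeric(x)) {
    x
  } else if (all(c("hcr_signal", "background") %in% names(x))) {
    x$hcr_signal / x$background
  } else if ("mean_intensity" %in% names(x)) {
    if (is.null(background_level)) stop("background_level required")
    signal_to_background(x, background_level)
  } else stop("cannot extract ratios from input")
  if (!length(r)) stop("ratio_ecdf needs at least one value")
  stats::ecdf(r)
}

#' Probe x taxon tagging matrix
#'
#' Rows are detection sequences, columns taxa; entries are the percentage
#' of cells of that taxon experimentally tagged by the probe. Each probe
#' designates one perfectly-matching pair (PMP), the taxon whose rRNA is
#' perfectly homologous to the probe.
#'
#' @param tagging Numeric matrix (probes x taxa), entries in `[0, 100]`.
#' @param pmp Named character vector: probe -> its PMP taxon (one each).
#' @return Object of class `probe_matrix`.
#' @export
probe_matrix <- function(tagging, pmp) {
  tagging <- as.matrix(tagging)
  if (any(tagging < 0 | tagging > 100)) {
    stop("tagging percentages must be in [0, 100]")
  }
  if (!all(rownames(tagging) %in% names(pmp)) ||
      !all(pmp[rownames(tagging)] %in% colnames(tagging))) {
    stop("every probe needs exactly one PMP column present in the matrix")
  }
  structure(list(tagging = tagging, pmp = pmp[rownames(tagging)]),
            class = "probe_matrix")
}

#' Select an orthogonal probe set
#'
#' A probe is admissible when its PMP entry reaches the detection floor
#' (84% by default) and every off-target entry stays within
#' `offtarget_max`, except for explicitly whitelisted probe-taxon pairs
#' (small documented cross-reactions such as a 0.3% tagging of a
#' non-target). When two admissible probes share a PMP taxon, the one with
#' the lower maximum off-target tagging wins — the rule that rejects a
#' promiscuous probe in favour of an orthogonal one covering the same
#' taxon.
#'
#' @param pm A [probe_matrix()].
#' @param pmp_min PMP detection floor, percent (default 84).
#' @param offtarget_max Maximum tolerated off-target tagging, percent.
#' @param exceptions data.frame with columns `probe`, `taxon` of tolerated
#'   off-target pairs (ignored in the admissibility check, listed in the
#'   report).
#' @param required_taxa Taxa that must end up covered; an uncoverable taxon
#'   raises an error listing the failing entries.
#' @return List: `selected` (probe -> taxon), `report` (per-probe
#'   admissibility table), `exceptions_used`.
#' @export
select_probe_set <- function(pm, pmp_min = 84, offtarget_max = 5,
                             exceptions = NULL, required_taxa = NULL) {
  stopifnot(inherits(pm, "probe_matrix"),
            pmp_min >= 0, pmp_min <= 100, offtarget_max >= 0)
  tg <- pm$tagging
  probes <- rownames(tg)
  rep_rows <- lapply(probes, function(p) {
    target <- pm$pmp[[p]]
    off <- tg[p, setdiff(colnames(tg), target), drop = TRUE]
    tolerated <- rep(FALSE, length(off))
    names(tolerated) <- names(off)
    if (!is.null(exceptions)) {
      exc <- exceptions[exceptions$probe == p, , drop = FALSE]
      tolerated[names(off) %in% exc$taxon] <- TRUE
    }
    viol <- off[off > offtarget_max & !tolerated]
    data.frame(probe = p, pmp_taxon = target, pmp_pct = tg[p, target],
               max_offtarget = if (length(off)) max(off) else 0,
               n_violations = length(viol),
               admissible = tg[p, target] >= pmp_min & length(viol) == 0L,
               exceptions_used = sum(tolerated & off > offtarget_max))
  })
  report <- do.call(rbind, rep_rows)
  adm <- report[report$admissible, , drop = FALSE]
  selected <- character(0)
  for (taxon in unique(adm$pmp_taxon)) {
    cand <- adm[adm$pmp_taxon == taxon, , drop = FALSE]
    best <- cand$probe[order(cand$max_offtarget, cand$probe)][1L]
    selected[[taxon]] <- best
  }
  if (!is.null(required_taxa)) {
    missing <- setdiff(required_taxa, names(selected))
    if (length(missing)) {
      bad <- report[report$pmp_taxon %in% missing, , drop = FALSE]
      stop("no admissible probe for taxa: ", paste(missing, collapse = ", "),
           "; failing entries: ",
           paste(sprintf("%s(PMP %.1f%%, max off-target %.1f%%)",
                         bad$probe, bad$pmp_pct, bad$max_offtarget),
                 collapse = "; "))
    }
  }
  list(selected = selected, report = report,
       exceptions_used = sum(report$exceptions_used))
}
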