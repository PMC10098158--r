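## ---------------------------------------------------------------------------
## Hierarchical threshold gating, bead-based absolute counting and
## per-donor feature extraction.
## ---------------------------------------------------------------------------

#' Fit a gating cutpoint on a 1-D intensity vector
#'
#' Three methods: `fixed` returns the configured value; `quantile` returns
#' the stated quantile; `valley` places the cut at the minimum-density point
#' between the two largest modes of a kernel density estimate (useful for
#' bimodal fluorescence, typically on log-transformed intensities).
#'
#' @param intensities numeric vector of event intensities.
#' @param method `"fixed"`, `"valley"` or `"quantile"`.
#' @param params list: `value` (fixed), `prob` (quantile), `default`
#'   (valley fallback when the density is unimodal).
#' @return the cutpoint (intensity scalar).
#' @examples
#' x <- c(rnorm(500, 1, 0.2), rnorm(500, 3, 0.2))
#' fitCutpoint(x, "valley")
#' fitCutpoint(x, "quantile", list(prob = 0.5))
#' @export
fitCutpoint <- function(intensities, method = c("fixed", "valley", "quantile"),
                        params = list()) {
  method <- match.arg(method)
  .checkFinite(intensities, "intensities")
  if (method == "fixed") {
    if (is.null(params$value)) stop("fixed method needs params$value")
    return(params$value)
  }
  if (method == "quantile") {
    prob <- if (is.null(params$prob)) 0.5 else params$prob
    return(unname(stats::quantile(intensities, prob, type = 7)))
  }
  # valley
  if (length(intensities) < 100)
    stop("valley method needs at least 100 events")
  d <- stats::density(intensities)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  # ignore spurious tail bumps: a mode must reach 10% of the highest peak
  peaks <- peaks[y[peaks] >= 0.1 * max(y)]
  if (length(peaks) < 2) {
    fallback <- if (is.null(params$default)) stats::median(intensities)
                else params$default
    warning("density is unimodal; falling back to configured default cutpoint")
    return(fallback)
  }
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  d$x[between[which.min(y[between])]]
}

#' Build the default gate hierarchy for a staining panel
#'
#' Cutpoints are fixed at the geometric midpoint between the negative and
#' positive fluorescence component medians of the supplied model (the
#' synthetic data's known mixture midpoints); the CD5 channel gets a
#' three-way partition whose middle stratum operationalises "CD5 dim". The
#' lymphocyte gate is a forward/side-scatter rectangle.
#'
#' @param panel `"surface"`, `"intracellular"` or `"ki67"`.
#' @param fluor_model per-channel fluorescence model, see
#'   [fluorModelDefaults()].
#' @return a \linkS4class{GatingSpec}.
#' @export
defaultGates <- function(panel = c("surface", "intracellular", "ki67"),
                         fluor_model = fluorModelDefaults()) {
  panel <- match.arg(panel)
  fm <- fluor_model
  cut2 <- function(ch) exp(mean(fm[[ch]]$meanlogs[c("neg", "pos")]))
  cd5lo <- exp(mean(fm$CD5$meanlogs[c("neg", "dim")]))
  cd5hi <- exp(mean(fm$CD5$meanlogs[c("dim", "bright")]))
  g <- function(name, parent, channel, min, max)
    data.frame(name = name, parent = parent, channel = channel,
               min = min, max = max, stringsAsFactors = FALSE)
  lymph <- rbind(
    g("lymph_fsc", "root", "FSC-A", 6.0e4, 1.45e5),
    g("lymph", "lymph_fsc", "SSC-A", 1.5e4, 8.5e4),
    g("cd3", "lymph", "CD3", cut2("CD3"), Inf))
  sub57 <- function(s) rbind(
    g(paste0(s, "_57"), s, "CD57", cut2("CD57"), Inf),
    g(paste0(s, "_57_cd5dim"), paste0(s, "_57"), "CD5", cd5lo, cd5hi),
    g(paste0(s, "_57_cd94"), paste0(s, "_57"), "CD94", cut2("CD94"), Inf),
    g(paste0(s, "_57_cd56"), paste0(s, "_57"), "CD56", cut2("CD56"), Inf),
    g(paste0(s, "_57_klrg1"), paste0(s, "_57"), "KLRG1", cut2("KLRG1"), Inf))
  tab <- switch(panel,
    surface = rbind(
      g("tab", "cd3", "TCRab", cut2("TCRab"), Inf),
      g("tgd", "cd3", "TCRab", -Inf, cut2("TCRab")),
      g("cd4hi", "tab", "CD4", cut2("CD4"), Inf),
      g("cd4t", "cd4hi", "CD8", -Inf, cut2("CD8")),
      g("cd8hi", "tab", "CD8", cut2("CD8"), Inf),
      g("cd8t", "cd8hi", "CD4", -Inf, cut2("CD4")),
      g("dpt", "cd4hi", "CD8", cut2("CD8"), Inf),
      sub57("cd8t"), sub57("cd4t"), sub57("tgd")),
    intracellular = rbind(
      g("cd4hi", "cd3", "CD4", cut2("CD4"), Inf),
      g("cd4t", "cd4hi", "CD8", -Inf, cut2("CD8")),
      g("cd8hi", "cd3", "CD8", cut2("CD8"), Inf),
      g("cd8t", "cd8hi", "CD4", -Inf, cut2("CD4")),
      do.call(rbind, lapply(c("cd4t", "cd8t"), function(s) rbind(
        g(paste0(s, "_ra"), s, "CD45RA", cut2("CD45RA"), Inf),
        g(paste0(s, "_ifng"), s, "IFNg", cut2("IFNg"), Inf),
        g(paste0(s, "_perf"), s, "Perforin", cut2("Perforin"), Inf))))),
    ki67 = rbind(
      g("cd4hi", "cd3", "CD4", cut2("CD4"), Inf),
      g("cd8hi", "cd3", "CD8", cut2("CD8"), Inf),
      g("cd8t", "cd8hi", "CD4", -Inf, cut2("CD4")),
      g("cd8t_57", "cd8t", "CD57", cut2("CD57"), Inf),
      g("cd8t_klrg1", "cd8t", "KLRG1", cut2("KLRG1"), Inf),
      g("cd8t_ki67", "cd8t", "Ki67", cut2("Ki67"), Inf)))
  methods::new("GatingSpec", gates = rbind(lymph, tab))
}

#' Apply a hierarchical gating specification to an event table
#'
#' An event belongs to a gate iff it belongs to the gate's parent and its
#' intensity on the gate's channel lies in `[min, max)`. Bead events are
#' excluded from the root. Returns the full per-event membership matrix plus
#' per-gate counts.
#'
#' @param sample a \linkS4class{CytoSample}.
#' @param gates a \linkS4class{GatingSpec}.
#' @return list with `membership` (logical events x gates matrix) and
#'   `counts` (named integer vector).
#' @export
applyGates <- function(sample, gates) {
  stopifnot(methods::is(sample, "CytoSample"), methods::is(gates, "GatingSpec"))
  g <- gateTable(gates)
  ex <- intensities(sample)
  missing <- setdiff(unique(g$channel), colnames(ex))
  if (length(missing))
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  n <- nrow(ex)
  memb <- matrix(FALSE, n, nrow(g), dimnames = list(NULL, g$name))
  root <- !isBead(sample)
  for (i in seq_len(nrow(g))) {
    parent <- if (g$parent[i] == "root") root else memb[, g$parent[i]]
    x <- ex[, g$channel[i]]
    memb[, i] <- parent & x >= g$min[i] & x < g$max[i]
  }
  list(membership = memb, counts = colSums(memb))
}

#' Bead-normalised absolute cell count
#'
#' Count beads are spiked at a known concentration; the cell concentration
#' follows from the ratio of gated cell events to bead events:
#' cells/uL = gated / beads x beads_per_uL, reported per liter of blood
#' (x 1e6).
#'
#' @param gatedEvents number of gated cell events.
#' @param beadEvents number of bead events (> 0).
#' @param beadsPerUl bead concentration, beads per microliter.
#' @return cells per liter.
#' @examples
#' absoluteCount(5000, 2500, 50)  # 100 cells/uL = 1e8 cells/L
#' @export
absoluteCount <- function(gatedEvents, beadEvents, beadsPerUl) {
  if (any(beadEvents <= 0))
    stop("beadEvents must be > 0: bead normalization impossible")
  gatedEvents / beadEvents * beadsPerUl * 1e6
}

.pct <- function(num, den) if (is.na(den) || den == 0) NA_real_ else 100 * num / den

#' Extract per-donor immunophenotype features from gated samples
#'
#' Computes the feature vector driving classification and group statistics:
#' bead-normalised absolute counts, the CD4:CD8 ratio, %CD8+CD57+ of
#' lymphocytes, NK-receptor marker percentages within the CD57+ fraction of
#' the CD4+, CD8+ and gamma-delta (CD3+TCRab-) subsets, CD57+KLRG1+
#' percentages per subset, and -- when the stimulation panels are supplied --
#' Ki67 percentages per CD57/KLRG1 stratum and IFN-g / perforin percentages
#' per subset and CD45RA fraction. Zero-denominator features are returned as
#' `NA` (flagged missing), never as 0.
#'
#' @param surface surface-panel \linkS4class{CytoSample} (required).
#' @param intracellular,ki67 optional stimulation-panel samples.
#' @param fluor_model fluorescence model used to build the fixed gates.
#' @param gates optional surface-panel \linkS4class{GatingSpec} overriding
#'   the default.
#' @param beadsPerUl bead concentration for absolute counts.
#' @return one-row `data.frame` of features.
#' @export
computeFeatures <- function(surface, intracellular = NULL, ki67 = NULL,
                            fluor_model = fluorModelDefaults(), gates = NULL,
                            beadsPerUl = 50) {
  stopifnot(panelType(surface) == "surface")
  if (is.null(gates)) gates <- defaultGates("surface", fluor_model)
  ag <- applyGates(surface, gates)
  cnt <- ag$counts
  memb <- ag$membership
  beadN <- sum(isBead(surface))
  cntOf <- function(nm) unname(cnt[nm])

  lymphN <- cntOf("lymph")
  feat <- data.frame(
    donor_id = surface@donorId, visit = surface@visit,
    visit_date = surface@visitDate,
    lymph_count_per_L = if (beadN > 0) absoluteCount(lymphN, beadN, beadsPerUl) else NA_real_,
    t_count_per_L = if (beadN > 0) absoluteCount(cntOf("cd3"), beadN, beadsPerUl) else NA_real_,
    cd4_count_per_L = if (beadN > 0) absoluteCount(cntOf("cd4t"), beadN, beadsPerUl) else NA_real_,
    cd8_count_per_L = if (beadN > 0) absoluteCount(cntOf("cd8t"), beadN, beadsPerUl) else NA_real_,
    cd4_cd8_ratio = if (cntOf("cd8t") > 0) cntOf("cd4t") / cntOf("cd8t") else NA_real_,
    pct_cd8cd57_of_lymph = .pct(cntOf("cd8t_57"), lymphN),
    stringsAsFactors = FALSE)

  for (s in c("cd8t", "cd4t", "tgd")) {
    short <- c(cd8t = "cd8", cd4t = "cd4", tgd = "gd")[[s]]
    n57 <- cntOf(paste0(s, "_57"))
    feat[[paste0("pct_cd5dim_", short, "57")]] <-
      .pct(cntOf(paste0(s, "_57_cd5dim")), n57)
    feat[[paste0("pct_cd94_", short, "57")]] <-
      .pct(cntOf(paste0(s, "_57_cd94")), n57)
    feat[[paste0("pct_cd56_", short, "57")]] <-
      .pct(cntOf(paste0(s, "_57_cd56")), n57)
    feat[[paste0("pct_klrg1_", short, "57")]] <-
      .pct(cntOf(paste0(s, "_57_klrg1")), n57)
    feat[[paste0("pct_cd57klrg1_", short)]] <-
      .pct(cntOf(paste0(s, "_57_klrg1")), cntOf(s))
  }

  if (!is.null(ki67)) {
    stopifnot(panelType(ki67) == "ki67")
    kg <- applyGates(ki67, defaultGates("ki67", fluor_model))
    km <- kg$membership
    cd8 <- km[, "cd8t"]
    s57 <- km[, "cd8t_57"]; k1 <- km[, "cd8t_klrg1"]; kpos <- km[, "cd8t_ki67"]
    strata <- list(`57n_k1n` = cd8 & !s57 & !k1,
                   `57n_k1p` = cd8 & !s57 & k1,
                   `57p_k1p` = cd8 & s57 & k1)
    for (nm in names(strata))
      feat[[paste0("pct_ki67_cd8_", nm)]] <-
        .pct(sum(kpos & strata[[nm]]), sum(strata[[nm]]))
  }

  if (!is.null(intracellular)) {
    stopifnot(panelType(intracellular) == "intracellular")
    ig <- applyGates(intracellular, defaultGates("intracellular", fluor_model))
    im <- ig$membership
    for (s in c("cd8t", "cd4t")) {
      short <- sub("t$", "", s)
      sub <- im[, s]
      ra <- im[, paste0(s, "_ra")]
      ifng <- im[, paste0(s, "_ifng")]
      perf <- im[, paste0(s, "_perf")]
      feat[[paste0("pct_ifng_", short)]] <- .pct(sum(ifng), sum(sub))
      feat[[paste0("pct_perforin_", short)]] <- .pct(sum(perf), sum(sub))
      feat[[paste0("pct_dual_", short)]] <- .pct(sum(ifng & perf), sum(sub))
      for (rl in c("ra_pos", "ra_neg")) {
        stratum <- if (rl == "ra_pos") sub & ra else sub & !ra
        feat[[paste0("pct_ifng_", short, "_", rl)]] <-
          .pct(sum(ifng & stratum), sum(stratum))
        feat[[paste0("pct_perforin_", short, "_", rl)]] <-
          .pct(sum(perf & stratum), sum(stratum))
      }
    }
  }
  feat
}

#' Gate an entire synthetic cohort into a feature table
#'
#' Materialises each donor-visit sample in turn (events are regenerated
#' deterministically, gated, then discarded, keeping memory flat), and
#' returns one feature row per donor visit. Stimulation panels are gated
#' for patient donors when requested.
#'
#' @param cohort an \linkS4class{LGLCohort}.
#' @param visits integer vector of visit indices (default: all configured).
#' @param panels character subset of
#'   `c("surface", "intracellular", "ki67")`; the surface panel is always
#'   gated.
#' @param nEvents optional per-sample non-bead event count override.
#' @param verbose print a progress line every 25 donors.
#' @return `data.frame` of features with `donor_id`, `group`, `visit`
#'   leading columns.
#' @export
gateCohort <- function(cohort, visits = NULL, panels = "surface",
                       nEvents = NULL, verbose = FALSE) {
  dd <- donors(cohort)
  cfg <- cohort@config
  fm <- cfg$fluor_model
  gates <- defaultGates("surface", fm)
  if (is.null(visits)) visits <- seq_len(cfg$visit_model$n_visits)
  rows <- list()
  for (i in seq_len(nrow(dd))) {
    if (verbose && i %% 25 == 0) message("  gating donor ", i, "/", nrow(dd))
    for (v in visits) {
      if (v > dd$n_visits[i]) next
      surf <- simulateEvents(cohort, dd$donor_id[i], v, "surface", nEvents)
      ic <- k67 <- NULL
      if (dd$group[i] != "HC") {
        if ("intracellular" %in% panels)
          ic <- simulateEvents(cohort, dd$donor_id[i], v, "intracellular", nEvents)
        if ("ki67" %in% panels)
          k67 <- simulateEvents(cohort, dd$donor_id[i], v, "ki67", nEvents)
      }
      f <- computeFeatures(surf, intracellular = ic, ki67 = k67,
                           fluor_model = fm, gates = gates,
                           beadsPerUl = cfg$beads_per_uL)
      f <- cbind(data.frame(group = dd$group[i], stringsAsFactors = FALSE), f)
      rows[[length(rows) + 1L]] <- f
    }
  }
  out <- do.call(.rbindFill, list(rows))
  out[order(out$donor_id, out$visit), , drop = FALSE]
}

## rbind data.frames whose column sets may differ (stimulation panels are
## only acquired for patients); missing columns become NA
.rbindFill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    d[cols]
  }))
}
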