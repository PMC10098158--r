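## ---------------------------------------------------------------------------
## End-to-end orchestration: simulate -> gate -> classify -> serology ->
## HLA -> statistics, with report tables shaped like the study's summary
## tables. All randomness flows from one seed; outputs are pure functions
## of (config, seed).
## ---------------------------------------------------------------------------

## weak content checksum so every written artifact can be tied to its config
.configHash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 997)) %%
            .Machine$integer.max)
}

.medianRange <- function(x, digits = 3) {
  x <- x[!is.na(x)]
  if (!length(x)) return("NA")
  sprintf("%s (%s-%s)", signif(stats::median(x), digits),
          signif(min(x), digits), signif(max(x), digits))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates a cohort, gates every donor visit into features, derives
#' healthy-control thresholds, classifies patients T-LGL_HIGH / LOW, calls
#' seropositivity from the simulated ELISA plates, scans HLA carriage
#' association using the predicted labels, runs the rank factorial test of
#' CD57+KLRG1+ frequency (group x T cell subset), and assembles
#' demographics / T-LGL / HLA / serology report tables. When `outDir` is
#' given, every table is written as CSV (thresholds as JSON) together with
#' a manifest recording the seed and a config checksum.
#'
#' @param config generator configuration from [cohortConfig()].
#' @param seed integer master seed.
#' @param outDir optional output directory (created if needed).
#' @param panels panels to gate (surface always; add `"intracellular"`,
#'   `"ki67"`).
#' @param stages named logical toggles: `serology`, `hla`, `stats`.
#' @param verbose log per-stage progress and counts.
#' @return list with `cohort`, `features`, `thresholds`,
#'   `classification`, `serology`, `hla_scan`, `stats`, `tables` (named
#'   list of report `data.frame`s), `seed`, `config_hash`.
#' @export
runPipeline <- function(config = cohortConfig(), seed = 1L, outDir = NULL,
                        panels = "surface",
                        stages = c(serology = TRUE, hla = TRUE, stats = TRUE),
                        verbose = FALSE) {
  note <- function(...) if (verbose) message("[lglpheno] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  note("simulate: seed ", seed)
  cohort <- stage("simulate", simulateCohort(config, seed))
  dd <- donors(cohort)
  note("simulate: ", nrow(dd), " donors")

  features <- stage("gate", gateCohort(cohort, panels = panels,
                                       verbose = verbose))
  note("gate: ", nrow(features), " donor-visit feature rows")

  hc1 <- features[features$group == "HC" & features$visit == 1, ]
  thresholds <- stage("classify", deriveThresholds(hc1))
  classification <- stage("classify",
                          classifyCohort(features, thresholds))
  note("classify: ", sum(classification$label == "HIGH"), " HIGH of ",
       nrow(classification))

  sero <- hla <- statsOut <- NULL
  labels <- classification$label
  names(labels) <- classification$donor_id

  if (isTRUE(stages[["serology"]])) {
    sero <- stage("serology", {
      plate <- serologyPlates(cohort)
      fc <- plateFoldChanges(plate)
      refFc <- .plateFoldChanges(plate, "reference")
      cutoffs <- deriveSerologyCutoffs(refFc)
      calls <- callSeropositivity(fc, cutoffs)
      pat <- calls[calls$sample_id %in% names(labels), ]
      groupsVec <- c(labels,
                     stats::setNames(dd$group, dd$donor_id)[dd$group == "HC"])
      list(calls = calls, cutoffs = cutoffs,
           summary = seroprevalence(pat, groupsVec[pat$sample_id]))
    })
    note("serology: ", sero$summary$prevalence$positive, "/",
         sero$summary$prevalence$n, " patients seropositive")
  }

  if (isTRUE(stages[["hla"]])) {
    hla <- stage("hla", hlaAssociationScan(genotypes(cohort), labels))
    note("hla: ", nrow(hla), " alleles retained")
  }

  if (isTRUE(stages[["stats"]])) {
    statsOut <- stage("stats", .pipelineStats(features, labels))
  }

  tables <- .reportTables(dd, features, classification, sero, hla)
  result <- list(cohort = cohort, features = features,
                 thresholds = thresholds, classification = classification,
                 serology = sero, hla_scan = hla, stats = statsOut,
                 tables = tables, seed = as.integer(seed),
                 config_hash = .configHash(config))
  if (!is.null(outDir)) .writeBundle(result, outDir, cohort)
  result
}

## long-format CD57+KLRG1+ frequency across subsets for the factorial test
.pipelineStats <- function(features, labels) {
  f1 <- features[features$visit == 1, ]
  grp <- ifelse(f1$group == "HC", "HC", labels[f1$donor_id])
  long <- do.call(rbind, lapply(c("cd4", "cd8", "gd"), function(s)
    data.frame(donor_id = f1$donor_id, group = grp, subset = s,
               value = f1[[paste0("pct_cd57klrg1_", s)]],
               stringsAsFactors = FALSE)))
  srh <- scheirerRayHare(long$value, long$group, long$subset)
  posthoc <- dunnPosthoc(long$value, long$group, adjust = "tukey")
  list(cd57klrg1_by_subset = list(data = long, srh = srh,
                                  posthoc = posthoc))
}

.reportTables <- function(dd, features, classification, sero, hla) {
  f1 <- features[features$visit == 1, ]
  ibm <- f1$group != "HC"
  demog <- data.frame(
    row = c("Number", "Age years median (range)", "Males:Females",
            "Lymphocyte count/L median (range)",
            "T cells/L median (range)", "CD4+ count/L median (range)",
            "CD8+ count/L median (range)", "CD4:CD8 ratio median (range)"),
    HC = c(sum(!ibm),
           .medianRange(dd$age[dd$group == "HC"]),
           paste(sum(dd$sex == "M" & dd$group == "HC"),
                 sum(dd$sex == "F" & dd$group == "HC"), sep = ":"),
           .medianRange(f1$lymph_count_per_L[!ibm]),
           .medianRange(f1$t_count_per_L[!ibm]),
           .medianRange(f1$cd4_count_per_L[!ibm]),
           .medianRange(f1$cd8_count_per_L[!ibm]),
           .medianRange(f1$cd4_cd8_ratio[!ibm])),
    IBM = c(sum(ibm),
            .medianRange(dd$age[dd$group != "HC"]),
            paste(sum(dd$sex == "M" & dd$group != "HC"),
                  sum(dd$sex == "F" & dd$group != "HC"), sep = ":"),
            .medianRange(f1$lymph_count_per_L[ibm]),
            .medianRange(f1$t_count_per_L[ibm]),
            .medianRange(f1$cd4_count_per_L[ibm]),
            .medianRange(f1$cd8_count_per_L[ibm]),
            .medianRange(f1$cd4_cd8_ratio[ibm])),
    stringsAsFactors = FALSE)

  lab <- classification$label
  names(lab) <- classification$donor_id
  cls <- ifelse(f1$group == "HC", "HC", lab[f1$donor_id])
  pct57 <- f1$pct_cd8cd57_of_lymph
  # %CD8+CD57+ is taken of lymphocytes, so the absolute count follows from
  # the lymphocyte concentration directly
  cd857count <- f1$lymph_count_per_L * pct57 / 100
  tlgl <- do.call(rbind, lapply(c("HC", "LOW", "HIGH"), function(g) {
    idx <- cls == g
    data.frame(group = g, n = sum(idx),
               lymph_count = .medianRange(f1$lymph_count_per_L[idx]),
               cd8cd57_count = .medianRange(cd857count[idx]),
               pct_cd8cd57_median = round(stats::median(pct57[idx],
                                                        na.rm = TRUE), 2),
               pct_cd8cd57_p95 = round(unname(stats::quantile(pct57[idx], 0.95,
                                                              na.rm = TRUE)), 2),
               pct_cd8cd57_range = .medianRange(pct57[idx]),
               stringsAsFactors = FALSE)
  }))

  tables <- list(demographics = demog, tlgl_summary = tlgl,
                 classification = classification)
  if (!is.null(hla)) tables$hla_scan <- hla
  if (!is.null(sero)) {
    s <- sero$summary
    tables$serology <- data.frame(
      group = rownames(s$by_group), n = s$by_group$n,
      positive = s$by_group$positive, pct = round(s$by_group$pct, 1),
      stringsAsFactors = FALSE)
    attr(tables$serology, "association") <-
      c(odds_ratio = s$odds_ratio, fisher_p = s$fisher_p)
  }
  tables
}

.writeBundle <- function(result, outDir, cohort) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# lglpheno seed=%d config=%s", result$seed,
                 result$config_hash)
  wr <- function(df, file) {
    path <- file.path(outDir, file)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  wr(donors(cohort), "donors.csv")
  wr(genotypes(cohort), "genotypes.csv")
  wr(serologyPlates(cohort), "elisa.csv")
  wr(result$features, "features.csv")
  wr(result$classification, "classification.csv")
  for (nm in setdiff(names(result$tables), "classification"))
    wr(result$tables[[nm]], paste0("table_", nm, ".csv"))
  thresholdsToJson(result$thresholds,
                   file.path(outDir, "thresholds.json"))
  manifest <- list(seed = result$seed, config_hash = result$config_hash,
                   tables = names(result$tables),
                   stages_run = c("simulate", "gate", "classify",
                                  if (!is.null(result$serology)) "serology",
                                  if (!is.null(result$hla_scan)) "hla",
                                  if (!is.null(result$stats)) "stats"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(outDir, "manifest.json"))
  invisible(outDir)
}
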