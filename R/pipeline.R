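# End-to-end orchestration: simulate -> QC -> classify -> copy number ->
# integrate -> benchmark -> stratify, with a run manifest and a plain-text
# report. Every stage output is CSV/JSON so each stage is independently
# inspectable and testable.

#' Run the full diagnostics pipeline on a synthetic cohort
#'
#' Generates (or accepts) a cohort, then runs every analysis stage and writes
#' all stage outputs plus a run manifest to `outdir`. Deterministic for a
#' fixed configuration seed.
#'
#' Stages: cohort simulation with failure processes; specimen QC gating;
#' metagene/SVM subgroup classification on QC-passing methylation and
#' expression profiles; three-platform copy-number calling; WNT consensus
#' integration and variant-review reconciliation; MLPA/array benchmarking
#' against iFISH; WHO-2016 classification, trial eligibility and risk-delta
#' accounting with turnaround thresholds.
#'
#' @param config a [cohort_config()] (or path to a YAML config readable by
#'   [read_cohort_config()]).
#' @param outdir output directory (created if needed).
#' @param cohort optionally, a pre-generated `mb_cohort` (must match
#'   `config`); by default the cohort is generated from `config`.
#' @param rnaseq run the RNA-seq (expression) classifier arm (default TRUE).
#' @param n_restarts,n_resamples classifier fitting controls, passed to
#'   [fit_metagenes()].
#' @return the run manifest (list of class `run_manifest`), invisibly the
#'   same object written to `manifest.json`: configuration hash, seed, stage
#'   timestamps, per-stage output files, package version.
#' @export
run_pipeline <- function(config, outdir, cohort = NULL, rnaseq = TRUE,
                         n_restarts = 50L, n_resamples = 1000L) {
  if (is.character(config)) config <- read_cohort_config(config)
  validate_cohort_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  files <- character()
  stamp <- function(stage) {
    stages[[stage]] <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  }
  run_stage <- function(stage, expr) {
    stamp(stage)
    tryCatch(expr, error = function(e) {
      marker <- file.path(outdir, paste0(stage, ".partial"))
      writeLines(conditionMessage(e), marker)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- simulate ---------------------------------------------------------------
  cohort <- run_stage("simulate", {
    if (is.null(cohort)) cohort <- generate_cohort(config)
    f <- write_cohort(cohort, outdir)
    files <- c(files, f)
    cohort
  })
  n <- nrow(cohort$patients)
  empty <- n == 0

  # -- qc ---------------------------------------------------------------------
  qc <- run_stage("qc", {
    qc <- assess_specimens(cohort$specimens)
    utils::write.csv(qc, file.path(outdir, "qc_decisions.csv"), row.names = FALSE)
    summary <- if (empty) list(n = 0) else unclass(summarize_qc(qc))
    if (!empty) summary$reasons <- as.list(summary$reasons)
    jsonlite::write_json(summary, file.path(outdir, "qc_summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    files <- c(files, qc_decisions = file.path(outdir, "qc_decisions.csv"),
               qc_summary = file.path(outdir, "qc_summary.json"))
    qc
  })

  # -- classify ---------------------------------------------------------------
  calls <- run_stage("classify", {
    calls <- data.frame(patient_id = character(), platform = character(),
                        label = character(), confidence = numeric(),
                        stringsAsFactors = FALSE)
    can_fit <- !empty &&
      all(table(factor(cohort$patients$true_subgroup,
                       levels = MB_SUBGROUPS)) >= 4)
    if (can_fit) {
      meth_ok <- qc$patient_id[qc$methylation_eligible]
      if (length(meth_ok) >= 16) {
        m <- cohort$methylation[, meth_ok, drop = FALSE]
        lab <- cohort$patients$true_subgroup[match(meth_ok,
                                                   cohort$patients$patient_id)]
        if (all(table(factor(lab, levels = MB_SUBGROUPS)) >= 4)) {
          model <- fit_metagenes(m, lab, nmf_seed = config$seed,
                                 n_restarts = n_restarts,
                                 n_resamples = n_resamples)
          res <- classify_cohort(m, model)
          calls <- rbind(calls, data.frame(
            patient_id = meth_ok, platform = "methylation",
            label = res$label, confidence = res$confidence,
            stringsAsFactors = FALSE))
        }
      }
      if (rnaseq) {
        rna_ok <- qc$patient_id[qc$rnaseq_eligible]
        if (length(rna_ok) >= 16) {
          x <- cohort$expression[, rna_ok, drop = FALSE]
          lab <- cohort$patients$true_subgroup[match(rna_ok,
                                                     cohort$patients$patient_id)]
          if (all(table(factor(lab, levels = MB_SUBGROUPS)) >= 4)) {
            emodel <- fit_metagenes(x, lab, nmf_seed = config$seed + 2L,
                                    n_restarts = n_restarts,
                                    n_resamples = n_resamples,
                                    platform = "rnaseq")
            res <- classify_cohort(x, emodel)
            calls <- rbind(calls, data.frame(
              patient_id = rna_ok, platform = "rnaseq",
              label = res$label, confidence = res$confidence,
              stringsAsFactors = FALSE))
          }
        }
      }
    }
    utils::write.csv(calls, file.path(outdir, "subgroup_calls.csv"),
                     row.names = FALSE)
    files <- c(files, subgroup_calls = file.path(outdir, "subgroup_calls.csv"))
    calls
  })

  # -- copy number ------------------------------------------------------------
  cn <- run_stage("cn", {
    cn <- call_cohort_cn(cohort)
    utils::write.csv(cn, file.path(outdir, "cn_calls.csv"), row.names = FALSE)
    files <- c(files, cn_calls = file.path(outdir, "cn_calls.csv"))
    cn
  })

  # -- integrate --------------------------------------------------------------
  integrated <- run_stage("integrate", {
    integrated <- integrate_cohort(cohort, qc, calls, cn)
    utils::write.csv(integrated$consensus, file.path(outdir, "consensus.csv"),
                     row.names = FALSE)
    utils::write.csv(integrated$records, file.path(outdir, "integrated.csv"),
                     row.names = FALSE)
    vr <- cohort$patients[, c("patient_id", "local_variant", "central_variant")]
    utils::write.csv(vr, file.path(outdir, "variant_review.csv"),
                     row.names = FALSE)
    files <- c(files, consensus = file.path(outdir, "consensus.csv"),
               integrated = file.path(outdir, "integrated.csv"),
               variant_review = file.path(outdir, "variant_review.csv"))
    integrated
  })

  # -- benchmark --------------------------------------------------------------
  bench <- run_stage("bench", {
    bench <- if (empty) NULL else benchmark_cn_platforms(cn)
    jsonlite::write_json(bench, file.path(outdir, "benchmark.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    files <- c(files, benchmark = file.path(outdir, "benchmark.json"))
    bench
  })

  # -- stratify ---------------------------------------------------------------
  strat <- run_stage("stratify", {
    strat <- stratify_cohort(cohort, integrated$records)
    utils::write.csv(strat$who, file.path(outdir, "who_classes.csv"),
                     row.names = FALSE)
    utils::write.csv(strat$eligibility, file.path(outdir, "eligibility.csv"),
                     row.names = FALSE)
    utils::write.csv(strat$risk_deltas, file.path(outdir, "risk_deltas.csv"),
                     row.names = FALSE)
    jsonlite::write_json(strat$funnel_json, file.path(outdir, "funnel.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    files <- c(files, who_classes = file.path(outdir, "who_classes.csv"),
               eligibility = file.path(outdir, "eligibility.csv"),
               risk_deltas = file.path(outdir, "risk_deltas.csv"),
               funnel = file.path(outdir, "funnel.json"))
    strat
  })

  # -- manifest ---------------------------------------------------------------
  stamp("manifest")
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("mbdx")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(file.path(outdir, "config.yaml"))),
    n_patients = n,
    stage_timestamps = stages,
    files = as.list(files)), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Integrate per-patient evidence and derive the WNT consensus
#'
#' Joins QC decisions, subgroup calls and copy-number calls into one
#' integrated per-patient table. Mutation and IHC fields come from the
#' (simulated) central workup; chromosome-6 status and subgroup calls come
#' from the pipeline's own assays. Final MYC/MYCN amplification status uses
#' iFISH where successful, falling back to the methylation array.
#'
#' @param cohort an `mb_cohort`.
#' @param qc data.frame from [assess_specimens()].
#' @param calls data.frame of subgroup calls (`patient_id`, `platform`,
#'   `label`, `confidence`).
#' @param cn data.frame from [call_cohort_cn()].
#' @return list with `panel` (WNT evidence panel), `consensus` (per-patient
#'   WNT consensus calls), `records` (integrated records consumed by
#'   [stratify_cohort()]).
#' @export
integrate_cohort <- function(cohort, qc, calls, cn) {
  p <- cohort$patients
  n <- nrow(p)
  get_call <- function(platform) {
    x <- calls[calls$platform == platform, ]
    x$label[match(p$patient_id, x$patient_id)]
  }
  meth_sub <- if (n) get_call("methylation") else character()
  rna_sub <- if (n) get_call("rnaseq") else character()
  chr6 <- cn[cn$platform == "array" & cn$target == "chr6", ]
  chr6_call <- chr6$status[match(p$patient_id, chr6$patient_id)] == "monosomy"
  amp_call <- function(tg) {
    # final amplification status: iFISH where successful, else array
    fi <- cn[cn$platform == "ifish" & cn$target == tg, ]
    ar <- cn[cn$platform == "array" & cn$target == tg, ]
    fi_st <- fi$status[match(p$patient_id, fi$patient_id)]
    ar_st <- ar$status[match(p$patient_id, ar$patient_id)]
    out <- ifelse(!is.na(fi_st) & fi_st != "fail", fi_st == "amplified",
                  ar_st == "amplified")
    out
  }
  panel <- data.frame(patient_id = p$patient_id,
                      ctnnb1_mut = p$ctnnb1_mut,
                      ihc_nuclear_pct = p$ihc_nuclear_pct,
                      chr6_monosomy = chr6_call,
                      meth_subgroup = meth_sub, rna_subgroup = rna_sub,
                      stringsAsFactors = FALSE)
  consensus <- call_cohort_wnt(panel)
  # consensus subgroup: methylation call, falling back to RNA-seq
  subgroup <- ifelse(!is.na(meth_sub) & meth_sub != "NC", meth_sub,
                     ifelse(!is.na(rna_sub) & rna_sub != "NC", rna_sub, NA))
  records <- data.frame(
    patient_id = p$patient_id, age_years = p$age_years,
    metastatic = p$metastatic, incomplete_resection = p$incomplete_resection,
    subgroup = subgroup, tp53_mut = p$tp53_mut,
    myc_amp = if (n) amp_call("MYC") else logical(),
    mycn_amp = if (n) amp_call("MYCN") else logical(),
    variant = p$central_variant, local_variant = p$local_variant,
    central_variant = p$central_variant,
    wnt_positive = consensus$status == "positive",
    surgery_to_receipt_days = cohort$timelines$surgery_to_receipt_days,
    receipt_to_report_days = cohort$timelines$receipt_to_report_days,
    stringsAsFactors = FALSE)
  list(panel = panel, consensus = consensus, records = records)
}

#' Stratify an integrated cohort
#'
#' WHO-2016 classes, trial-eligibility decisions and funnel, risk deltas and
#' per-stage turnaround thresholds for an integrated cohort.
#'
#' @param cohort an `mb_cohort` (timelines are read from it).
#' @param records integrated records from [integrate_cohort()].
#' @return list with `who`, `eligibility`, `funnel`, `risk_deltas`,
#'   `turnaround`, `funnel_json`.
#' @export
stratify_cohort <- function(cohort, records) {
  n <- nrow(records)
  who <- data.frame(patient_id = records$patient_id,
                    who_class = vapply(seq_len(n), function(i) {
                      classify_who2016(records$subgroup[i], records$tp53_mut[i])
                    }, character(1)),
                    stringsAsFactors = FALSE)
  if (!n) {
    who <- data.frame(patient_id = character(), who_class = character(),
                      stringsAsFactors = FALSE)
  }
  records$who_class <- who$who_class[match(records$patient_id, who$patient_id)]
  eligibility <- if (n) assess_cohort_eligibility(records) else
    data.frame(patient_id = character(), eligible = logical(),
               stringsAsFactors = FALSE)
  funnel <- if (n) cohort_accounting(eligibility) else NULL
  risk_deltas <- if (n) compute_cohort_risk_deltas(records) else
    data.frame(patient_id = character(), altered = logical(),
               stringsAsFactors = FALSE)
  turnaround <- NULL
  if (n >= 2) {
    tl <- cohort$timelines
    turnaround <- lapply(
      c(surgery_to_receipt = "surgery_to_receipt_days",
        fish_processing = "fish_processing_days",
        fish_reporting = "fish_reporting_days",
        histology_processing = "histology_processing_days",
        cpr_review = "cpr_review_days",
        receipt_to_report = "receipt_to_report_days"),
      function(col) {
        ts <- turnaround_thresholds(tl[[col]], tl$delay_reason)
        list(mean = ts$mean, sd = ts$sd, threshold = ts$threshold,
             n_late = ts$n_late,
             late_reasons = as.list(ts$late_reasons))
      })
  }
  funnel_json <- list(
    counts = if (is.null(funnel)) NULL else as.list(funnel$counts),
    arms = if (is.null(funnel)) NULL else as.list(funnel$arms),
    percent_eligible = if (is.null(funnel)) NULL else funnel$percent_eligible,
    turnaround = turnaround)
  list(who = who, eligibility = eligibility, funnel = funnel,
       risk_deltas = risk_deltas, turnaround = turnaround,
       funnel_json = funnel_json)
}

#' Write a human-readable run report
#'
#' Produces a single plain-text report from a completed run directory:
#' cohort composition, QC funnel, subgroup assignment, copy-number and
#' benchmarking tables, WNT consensus, variant review, eligibility funnel and
#' turnaround thresholds. All percentages show raw and rounded values. An
#' empty cohort produces a report with explicit empty-cohort notices.
#'
#' @param outdir a directory previously populated by [run_pipeline()].
#' @param path output file (default `report.txt` inside `outdir`).
#' @return invisibly, the path written.
#' @export
write_report <- function(outdir, path = file.path(outdir, "report.txt")) {
  manifest_path <- file.path(outdir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json in ", outdir, "; run the pipeline first",
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path)
  need <- c("cohort.csv", "qc_decisions.csv", "subgroup_calls.csv",
            "cn_calls.csv", "consensus.csv", "eligibility.csv",
            "who_classes.csv")
  missing <- need[!file.exists(file.path(outdir, need))]
  if (length(missing)) {
    stop("incomplete run; missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rd <- function(f) utils::read.csv(file.path(outdir, f),
                                    stringsAsFactors = FALSE)
  patients <- rd("cohort.csv")
  n <- nrow(patients)
  lines <- c(
    "== Run summary ==",
    sprintf("package mbdx %s, seed %s, %d patients",
            manifest$package_version, manifest$seed, n))
  if (n == 0) {
    lines <- c(lines, "", "EMPTY COHORT: no patients simulated;",
               "all downstream sections are empty.")
  }
  lines <- c(lines, "", "== Cohort composition ==")
  if (n) {
    tab <- table(patients$true_subgroup)
    lines <- c(lines, vapply(names(tab), function(s)
      sprintf("  %-8s %s", s, fmt_pct(tab[[s]], n)), character(1)))
  } else lines <- c(lines, "  (empty cohort)")

  qc <- rd("qc_decisions.csv")
  lines <- c(lines, "", "== Specimen QC ==")
  if (nrow(qc)) {
    s <- summarize_qc(qc)
    lines <- c(lines, vapply(names(s$counts), function(cl)
      sprintf("  %-22s %s", cl, fmt_pct(s$counts[[cl]], s$n)), character(1)))
  } else lines <- c(lines, "  (empty cohort)")

  calls <- rd("subgroup_calls.csv")
  lines <- c(lines, "", "== Molecular subgrouping ==")
  if (nrow(calls)) {
    for (pl in unique(calls$platform)) {
      x <- calls[calls$platform == pl, ]
      ok <- sum(x$label != "NC")
      lines <- c(lines, sprintf("  %-12s classified %s", pl,
                                fmt_pct(ok, nrow(x))))
    }
  } else lines <- c(lines, "  (no classifiable samples)")

  cn <- rd("cn_calls.csv")
  lines <- c(lines, "", "== Copy number ==")
  if (nrow(cn)) {
    for (pl in c("ifish", "mlpa", "array")) {
      x <- cn[cn$platform == pl & cn$target %in% c("MYC", "MYCN"), ]
      lines <- c(lines, sprintf("  %-6s amplified %d / fail %d / assays %d", pl,
                                sum(x$status == "amplified"),
                                sum(x$status == "fail"), nrow(x)))
    }
  } else lines <- c(lines, "  (no assays)")

  lines <- c(lines, "", "== Benchmarking vs iFISH ==")
  bench_path <- file.path(outdir, "benchmark.json")
  bench <- if (file.exists(bench_path)) jsonlite::read_json(bench_path) else NULL
  if (length(bench)) {
    for (row in bench) {
      lines <- c(lines, sprintf(
        "  %-5s %-6s sens %s spec %s (tp=%d fp=%d fn=%d tn=%d)",
        row$target, row$platform,
        ifelse(is.null(row$sensitivity), "NA", row$sensitivity),
        ifelse(is.null(row$specificity), "NA", row$specificity),
        row$tp, row$fp, row$fn, row$tn))
    }
  } else lines <- c(lines, "  (not computed)")

  cons <- rd("consensus.csv")
  lines <- c(lines, "", "== WNT consensus ==")
  if (nrow(cons)) {
    lines <- c(lines, sprintf("  positive %s, indeterminate %d",
                              fmt_pct(sum(cons$status == "positive"), nrow(cons)),
                              sum(cons$status == "indeterminate")))
  } else lines <- c(lines, "  (empty cohort)")

  vr <- rd("variant_review.csv")
  lines <- c(lines, "", "== Variant review ==")
  if (nrow(vr)) {
    s <- reconcile_variants(vr)
    lines <- c(lines,
               sprintf("  changed  %s", fmt_pct(s$counts[["changed"]],
                                                s$n_local_assigned)),
               sprintf("  assigned %s", fmt_pct(s$counts[["assigned"]], s$n)),
               sprintf("  combined %s",
                       fmt_pct(s$counts[["changed"]] + s$counts[["assigned"]],
                               s$n)))
  } else lines <- c(lines, "  (empty cohort)")

  who <- rd("who_classes.csv")
  lines <- c(lines, "", "== WHO 2016 classification ==")
  if (nrow(who)) {
    tab <- table(factor(who$who_class, levels = WHO_CLASSES))
    lines <- c(lines, vapply(names(tab), function(cl)
      sprintf("  %-16s %s", cl, fmt_pct(tab[[cl]], nrow(who))), character(1)))
  } else lines <- c(lines, "  (empty cohort)")

  elig <- rd("eligibility.csv")
  lines <- c(lines, "", "== Trial eligibility ==")
  if (nrow(elig)) {
    fu <- cohort_accounting(elig)
    lines <- c(lines, vapply(names(fu$counts), function(nm)
      sprintf("  %-28s %d", nm, fu$counts[[nm]]), character(1)),
      sprintf("  eligible of age-eligible     %s",
              fmt_pct(fu$counts[["eligible"]], fu$counts[["age_eligible"]])))
  } else lines <- c(lines, "  (empty cohort)")

  writeLines(lines, path)
  invisible(path)
}
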