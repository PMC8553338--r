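# End-to-end demonstration of the discrimination argument on packaged
# defaults: the "which model explains the knock-in data" pipeline.

#' Run the full model-discrimination pipeline on packaged defaults
#'
#' Generates synthetic wild-type vs S513A observations under the
#' model 1 defaults, then assembles the whole argument: (i) free
#' Regnase-1 is matched across genotypes at late times while total
#' Regnase-1 is lower in S513A; (ii) at that matched free-protein level,
#' model 1 predicts equal target mRNA across genotypes (consistent with
#' the data) and model 2 predicts strictly lower mRNA in wild type
#' (inconsistent); (iii) the wild-type total-Regnase-1 trajectory dips
#' below baseline within the first hour of stimulation and overshoots it
#' by 4 h. Deterministic for a fixed `seed`.
#'
#' @param seed integer seed for the synthetic noise.
#' @param path optional file path; when given, the report is written
#'   there as JSON.
#' @param cv,replicates noise level and replicate count of the synthetic
#'   data (defaults 0.1 and 3, the study-like design).
#' @return A `reg1_report` list (invisibly when `path` is given):
#'   qualitative ratios from the noiseless model, the two model
#'   verdicts, and replicate-mean summaries of the noisy data.
#' @examples
#' rep <- reproduce_discrimination_argument(seed = 1)
#' rep$model1_consistent
#' @export
reproduce_discrimination_argument <- function(seed = 1, path = NULL,
                                              cv = 0.1, replicates = 3) {
  params_wt <- default_parameters("wt")
  params_sa <- default_parameters("s513a")
  params_m2 <- default_parameters("wt", kind = "model2")
  profile <- default_profile()
  times <- c(0, 0.5, 2, 4)

  clean <- simulate_observations(params_wt, params_sa, profile,
                                 sample_times = times, cv = 0,
                                 replicates = 1)
  noisy <- simulate_observations(params_wt, params_sa, profile,
                                 sample_times = times, cv = cv,
                                 replicates = replicates, seed = seed)

  val <- function(tbl, g, tt, ob) {
    v <- tbl$value[tbl$genotype == g & tbl$time == tt & tbl$observable == ob]
    mean(v)
  }
  matched_X3 <- val(clean, "wt", 4, "free_reg1")
  v1 <- discriminate_models(params_wt, profile$s_input, matched_X3)
  v2 <- discriminate_models(params_m2, profile$s_input, matched_X3)

  noisy_means <- noisy |>
    dplyr::group_by(.data$genotype, .data$time, .data$observable) |>
    dplyr::summarise(mean_value = mean(.data$value), .groups = "drop")

  report <- list(
    seed = seed,
    parameter_provenance = "packaged illustrative defaults",
    total_reg1_dip_ratio_wt =
      val(clean, "wt", 0.5, "total_reg1") / val(clean, "wt", 0, "total_reg1"),
    total_reg1_overshoot_ratio_wt =
      val(clean, "wt", 4, "total_reg1") / val(clean, "wt", 0, "total_reg1"),
    total_reg1_sa_over_wt_4h =
      val(clean, "s513a", 4, "total_reg1") / val(clean, "wt", 4, "total_reg1"),
    free_reg1_wt_over_sa_4h =
      val(clean, "wt", 4, "free_reg1") / val(clean, "s513a", 4, "free_reg1"),
    il6_wt_over_sa_4h =
      val(clean, "wt", 4, "il6_mrna") / val(clean, "s513a", 4, "il6_mrna"),
    noisy_free_reg1_wt_over_sa_4h =
      val(noisy, "wt", 4, "free_reg1") / val(noisy, "s513a", 4, "free_reg1"),
    matched_X3 = matched_X3,
    model1_consistent = v1$consistent_with_no_difference,
    model2_consistent = v2$consistent_with_no_difference,
    model1_verdict = unclass(v1),
    model2_verdict = unclass(v2),
    noisy_replicate_means = noisy_means
  )
  class(report) <- "reg1_report"
  if (!is.null(path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    return(invisible(report))
  }
  report
}

#' @export
print.reg1_report <- function(x, ...) {
  cat("<reg1_report> seed ", x$seed, " (", x$parameter_provenance, ")\n",
      "  WT total Reg1: 0.5 h / 0 h = ", format(x$total_reg1_dip_ratio_wt),
      " (dip), 4 h / 0 h = ", format(x$total_reg1_overshoot_ratio_wt),
      " (overshoot)\n",
      "  S513A/WT total Reg1 at 4 h = ", format(x$total_reg1_sa_over_wt_4h), "\n",
      "  WT/S513A free Reg1 at 4 h = ", format(x$free_reg1_wt_over_sa_4h),
      " (matched)\n",
      "  WT/S513A Il6 mRNA at 4 h = ", format(x$il6_wt_over_sa_4h), "\n",
      "  model 1 consistent with no mRNA difference: ", x$model1_consistent, "\n",
      "  model 2 consistent with no mRNA difference: ", x$model2_consistent, "\n",
      sep = "")
  invisible(x)
}
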