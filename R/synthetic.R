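# Synthetic two-genotype observation tables emulating the study design:
# immunoblot-style Regnase-1 readouts (total, and the fast/slow-migrating
# fractions read as free vs 14-3-3-bound) and RT-qPCR-style Il6/Zc3h12a
# mRNA, at a few time points, three replicates, multiplicative noise.

#' Project a model state onto a measured observable
#'
#' `total_reg1` is `x3 + x4` (whole-protein immunoblot), `free_reg1` is
#' `x3` (fast-migrating band), `bound_reg1` is `x4` (slow-migrating
#' band; exposed for synthetic studies only — real gels read it only as
#' a shift), `il6_mrna` is `x1` and `zc3h12a_mrna` is `x2`.
#'
#' @param state numeric state `(x1, x2, x3, x4)`.
#' @param observable one of `"total_reg1"`, `"free_reg1"`, `"bound_reg1"`,
#'   `"il6_mrna"`, `"zc3h12a_mrna"`.
#' @return A single nonnegative number.
#' @export
observe_state <- function(state, observable) {
  observable <- match.arg(observable, OBSERVABLES)
  state <- as.numeric(state)
  switch(observable,
         total_reg1 = state[3] + state[4],
         free_reg1 = state[3],
         bound_reg1 = state[4],
         il6_mrna = state[1],
         zc3h12a_mrna = state[2])
}

# Lognormal factors with mean exactly 1 and coefficient of variation cv.
noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Generate a synthetic two-genotype observation table
#'
#' Integrates each genotype's model from its basal equilibrium through
#' the stimulation profile, samples the five observables at
#' `sample_times`, and multiplies each value by an independent lognormal
#' factor with mean 1 and coefficient of variation `cv`, drawing
#' `replicates` values per (genotype, time, observable) cell. With
#' `cv = 0` the table equals the noiseless model projections; with a
#' `seed` the table is fully reproducible.
#'
#' @param params_wt wild-type [model_parameters()].
#' @param params_sa S513A parameter set (S513A semantics are applied, so
#'   `d7 = d8 = d9 = 0` effectively).
#' @param profile a [signal_profile()].
#' @param sample_times observation times (h); default `c(0, 0.5, 2, 4)`,
#'   the study's design.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param replicates replicates per cell (default 3).
#' @param seed integer RNG seed; `NULL` uses the session RNG state.
#' @return A `reg1_observations` tibble with columns
#'   `genotype, time, observable, replicate, value` and the generating
#'   parameters, profile and noise specification as a `provenance`
#'   attribute.
#' @examples
#' obs <- simulate_observations(default_parameters("wt"),
#'                              default_parameters("s513a"),
#'                              cv = 0.1, seed = 7)
#' dplyr::count(obs, genotype, observable)
#' @export
simulate_observations <- function(params_wt, params_sa,
                                  profile = default_profile(),
                                  sample_times = c(0, 0.5, 2, 4),
                                  cv = 0.1, replicates = 3, seed = NULL) {
  stopifnot(inherits(params_wt, "reg1_params"),
            inherits(params_sa, "reg1_params"))
  if (length(sample_times) == 0) stop("`sample_times` must be nonempty", call. = FALSE)
  if (!is.numeric(cv) || cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)

  sample_times <- sort(unique(as.numeric(sample_times)))
  tc_times <- if (length(sample_times) == 1L) c(0, sample_times) else sample_times
  sets <- list(wt = list(params = params_wt, genotype = "wt"),
               s513a = list(params = params_sa, genotype = "s513a"))

  noiseless <- purrr::imap_dfr(sets, function(st, gname) {
    tc <- simulate_timecourse(st$params, profile, times = tc_times,
                              genotype = st$genotype)
    tc <- tc[tc$time %in% sample_times, ]
    tidyr::expand_grid(i = seq_len(nrow(tc)), observable = OBSERVABLES) |>
      dplyr::mutate(
        genotype = gname,
        time = tc$time[.data$i],
        mean = purrr::map2_dbl(.data$i, .data$observable, function(i, ob) {
          observe_state(as.numeric(tc[i, c("x1", "x2", "x3", "x4")]), ob)
        })
      ) |>
      dplyr::select("genotype", "time", "observable", "mean")
  })

  draw <- function() {
    tidyr::expand_grid(noiseless, replicate = seq_len(replicates)) |>
      dplyr::mutate(value = .data$mean * noise_factors(dplyr::n(), cv)) |>
      dplyr::select("genotype", "time", "observable", "replicate", "value")
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())

  attr(out, "provenance") <- list(
    params_wt = params_wt, params_sa = params_sa, profile = profile,
    noise = list(cv = cv, seed = seed, replicates = replicates)
  )
  class(out) <- c("reg1_observations", class(out))
  out
}

#' Read and write observation tables
#'
#' CSV with header `genotype,time,observable,replicate,value`, plus a
#' sidecar JSON provenance file (`<stem>_provenance.json`) recording the
#' generating parameters, profile and noise specification.
#'
#' @param obs a `reg1_observations` tibble.
#' @param path CSV file path.
#' @return `read_observations()` returns a `reg1_observations` tibble
#'   (with provenance when the sidecar exists); the writer returns
#'   `path` invisibly.
#' @name observations_io
NULL

#' @rdname observations_io
#' @export
write_observations <- function(obs, path) {
  readr::write_csv(obs[, c("genotype", "time", "observable", "replicate", "value")],
                   path)
  prov <- attr(obs, "provenance")
  if (!is.null(prov)) {
    doc <- list(
      params_wt = full_precision(unclass(prov$params_wt)[c(PARAM_FIELDS, "kind", "genotype")]),
      params_sa = full_precision(unclass(prov$params_sa)[c(PARAM_FIELDS, "kind", "genotype")]),
      profile = full_precision(unclass(prov$profile)[PROFILE_FIELDS]),
      noise = prov$noise
    )
    jsonlite::write_json(doc, provenance_path(path), auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

provenance_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_provenance.json")
}

#' @rdname observations_io
#' @export
read_observations <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           genotype = readr::col_character(),
                           observable = readr::col_character(),
                           .default = readr::col_double()
                         ))
  pp <- provenance_path(path)
  if (file.exists(pp)) {
    doc <- jsonlite::read_json(pp)
    restore <- function(d) {
      do.call(model_parameters,
              c(list(kind = d$kind, genotype = d$genotype %||% "wt"),
                purrr::map(d[PARAM_FIELDS], as.numeric)))
    }
    attr(out, "provenance") <- list(
      params_wt = restore(doc$params_wt),
      params_sa = restore(doc$params_sa),
      profile = do.call(signal_profile, c(
        purrr::map(doc$profile[setdiff(PROFILE_FIELDS, "post_pulse_mode")], as.numeric),
        list(post_pulse_mode = doc$profile$post_pulse_mode))),
      noise = doc$noise
    )
  }
  class(out) <- c("reg1_observations", class(out))
  out
}
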