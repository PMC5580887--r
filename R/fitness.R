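#' Relative fitness from competition flow-cytometry counts
#'
#' Estimates the per-generation selection coefficient of an evolved strain
#' competed against a fluorescent reference from cell counts at two
#' timepoints,
#' \deqn{s = \frac{1}{\tau}\,\ln\!\left(\frac{n_{e,f} - p\,n_{r,f}}{n_{r,f}}
#'          \cdot \frac{n_{r,i}}{n_{e,i} - p\,n_{r,i}}\right),}
#' where \eqn{\tau} is the assay length in generations and \eqn{p} is the
#' non-fluorescent proportion of reference cells (the correction used in the
#' high-temperature synthetic-medium assay, where 98.5% of reference cells
#' fluoresce, hence the default `p = 0.015` there; `p = 0` recovers the
#' uncorrected estimator).  Counts may be nonnegative reals (flow proportions
#' times totals), not only integers.
#'
#' @param ne_i,nr_i initial counts of the evolved and reference strain.
#' @param ne_f,nr_f final counts of the evolved and reference strain.
#' @param tau elapsed generations (> 0).
#' @param p non-fluorescent proportion of reference cells, in `[0, 1)`.
#' @return fitness per generation (finite scalar; vectorized over inputs).
#' @examples
#' estimate_fitness(100, 100, 400, 100, tau = 10)  # log(4)/10
#' @export
estimate_fitness <- function(ne_i, nr_i, ne_f, nr_f, tau, p = 0) {
  if (any(tau <= 0)) stop("'tau' must be positive")
  check_prob(p, "p")
  if (any(p >= 1)) stop("'p' must be < 1")
  if (any(c(ne_i, nr_i, ne_f, nr_f) <= 0))
    stop("all counts must be positive")
  ei <- ne_i - p * nr_i
  ef <- ne_f - p * nr_f
  if (any(ei <= 0))
    stop("corrected evolved count at the initial timepoint is <= 0")
  if (any(ef <= 0))
    stop("corrected evolved count at the final timepoint is <= 0")
  (1 / tau) * log((ef / nr_f) * (nr_i / ei))
}

#' Summarize replicate fitness measurements of a strain
#'
#' Returns the arithmetic mean and the error variance of that mean: the
#' unbiased sample variance of the replicates divided by the number of
#' replicates.  This is the per-founder error variance entering the
#' broad-sense variance partition, on the scale of the founder *mean* --
#' the scaling consistent with broad-sense heritabilities of fitness near 1
#' when technical error is small relative to genetic variation.
#'
#' @param values numeric vector of at least 2 replicate fitness measurements.
#' @return list with `mean`, `error_var` (variance of the mean), `n_reps`.
#' @examples
#' summarize_replicates(c(1, 2, 3, 4))  # mean 2.5, error_var (5/3)/4
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need >= 2 replicates to estimate the error variance")
  list(mean = mean(values), error_var = stats::var(values) / n, n_reps = n)
}

#' Fitness estimates from a two-timepoint competition count table
#'
#' Reads (or accepts) a long-format competition table with columns
#' `strain_id` (or `population_id`), `environment`, `timepoint_day`,
#' `count_evolved`, `count_reference`, and computes one fitness per
#' (strain, environment, replicate) from the earliest and latest timepoint,
#' with `tau = tau_per_day[environment] * elapsed days` and the
#' environment's non-fluorescent reference correction.
#'
#' @param competitions data frame or TSV path.
#' @param tau_per_day named generations per day per environment (the
#'   protocol gives roughly 10 at optimal and 9 at high temperature).
#' @param p_nonfluor named non-fluorescent reference fraction per
#'   environment (0 at OT; 0.015 at HT, where 98.5% of reference cells
#'   fluoresce).
#' @return data frame with `strain_id`, `environment`, `replicate`,
#'   `fitness`.
#' @export
fitness_from_competitions <- function(competitions,
                                      tau_per_day = c(OT = 10, HT = 9),
                                      p_nonfluor = c(OT = 0, HT = 0.015)) {
  df <- if (is.character(competitions))
    utils::read.delim(competitions, stringsAsFactors = FALSE) else competitions
  id_col <- if ("strain_id" %in% names(df)) "strain_id" else "population_id"
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  key <- interaction(df[[id_col]], df$environment, df$replicate, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    g <- g[order(g$timepoint_day), ]
    i <- 1L; f <- nrow(g)
    if (f < 2) stop("need counts at two or more timepoints")
    env <- g$environment[1]
    tau <- tau_per_day[[env]] * (g$timepoint_day[f] - g$timepoint_day[i])
    data.frame(strain_id = g[[id_col]][1], environment = env,
               replicate = g$replicate[1],
               fitness = estimate_fitness(g$count_evolved[i],
                                          g$count_reference[i],
                                          g$count_evolved[f],
                                          g$count_reference[f],
                                          tau = tau,
                                          p = p_nonfluor[[env]]))
  }))
  rownames(out) <- NULL
  out
}

#' Per-strain fitness summaries from a replicate measurement table
#'
#' Applies [summarize_replicates()] to every (strain, environment) group of a
#' long-format fitness table such as the one produced by
#' [simulate_measurements()].
#'
#' @param fitness_table data frame with columns `strain_id`, `environment`,
#'   `fitness` (and optionally `type`).
#' @param environment optional environment to restrict to.
#' @param type optional strain type to restrict to (`"founder"` or
#'   `"population"`).
#' @return data frame with `strain_id`, `environment`, `mean`, `error_var`,
#'   `n_reps`.
#' @export
summarize_fitness_table <- function(fitness_table, environment = NULL,
                                    type = NULL) {
  ft <- fitness_table
  if (!is.null(environment)) ft <- ft[ft$environment %in% environment, ]
  if (!is.null(type) && "type" %in% names(ft)) ft <- ft[ft$type %in% type, ]
  key <- interaction(ft$strain_id, ft$environment, drop = TRUE)
  sp <- split(ft, key)
  out <- do.call(rbind, lapply(sp, function(g) {
    if (nrow(g) >= 2) {
      s <- summarize_replicates(g$fitness)
    } else {
      s <- list(mean = g$fitness, error_var = NA_real_, n_reps = 1L)
    }
    data.frame(strain_id = g$strain_id[1], environment = g$environment[1],
               mean = s$mean, error_var = s$error_var, n_reps = s$n_reps)
  }))
  rownames(out) <- NULL
  out
}
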