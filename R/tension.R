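#' Cortical tension from micropipette aspiration (Young--Laplace)
#'
#' At the critical aspiration pressure the cortical tension follows from the
#' Young--Laplace balance between the pipette-scale and cell-scale curvature:
#' \deqn{T_c = \Delta P / (2 (1/R_p - 1/R_c))}
#' With \code{delta_P} in pascals and radii in micrometres the result is in
#' Pa um; 1 Pa um = 1e-3 mN/m, and both are reported.
#'
#' @param delta_P aspiration pressure difference (Pa), positive at
#'   aspiration.
#' @param R_p pipette radius (um).
#' @param R_c cell radius (um); must differ from \code{R_p}.
#' @return list with \code{Tc_Pa_um} and \code{Tc_mN_m}.
#' @export
laplace_tension <- function(delta_P, R_p, R_c) {
  if (any(R_p <= 0) || any(R_c <= 0))
    stop("radii must be positive")
  if (any(R_p == R_c))
    stop("R_p equal to R_c: Young-Laplace relation is singular")
  Tc <- delta_P / (2 * (1 / R_p - 1 / R_c))
  list(Tc_Pa_um = Tc, Tc_mN_m = Tc / 1000)
}

#' Fractional tension change between two groups with a bootstrap CI
#'
#' Reports \code{1 - mean(group_b) / mean(group_a)} (e.g. the fractional
#' reduction after jelly removal) with a seeded percentile bootstrap
#' confidence interval.
#'
#' @param group_a,group_b numeric vectors of tensions (same units).
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list with \code{fractional_change}, \code{ci} (length 2),
#'   \code{n_boot}.
#' @export
tension_ratio <- function(group_a, group_b, n_boot = 2000L, conf = 0.95,
                          seed = 1L) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  est <- 1 - mean(group_b) / mean(group_a)
  set.seed(as.integer(seed))
  reps <- replicate(n_boot, {
    a <- sample(group_a, replace = TRUE)
    b <- sample(group_b, replace = TRUE)
    1 - mean(b) / mean(a)
  })
  alpha <- (1 - conf) / 2
  list(fractional_change = est,
       ci = unname(stats::quantile(reps, c(alpha, 1 - alpha))),
       n_boot = n_boot)
}

#' Apply \code{\link{laplace_tension}} to a CSV of aspiration readings
#'
#' @param path CSV with columns \code{delta_P}, \code{R_p}, \code{R_c} and
#'   optionally \code{condition}.
#' @return data frame with appended tension columns.
#' @export
read_aspiration_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("delta_P", "R_p", "R_c")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns: ", paste(need, collapse = ", "))
  tc <- laplace_tension(df$delta_P, df$R_p, df$R_c)
  df$Tc_Pa_um <- tc$Tc_Pa_um
  df$Tc_mN_m <- tc$Tc_mN_m
  df
}
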