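#' Preset simulation designs for the benchmark studies
#'
#' The Monte-Carlo studies in this package revolve around four standard
#' grids; the presets build the corresponding design lists so they can be
#' run at any replication count:
#'
#' * `"dim0-small"`: the zero-dimensional model (all items i.i.d.
#'   Bernoulli(0.5)) at the small test-length / small sample-size corner,
#'   `J` in \{3, 4, 5\} x `N` in \{250, 500\}, continuity on. Type I error
#'   study.
#' * `"dim1-grid"`: unidimensional 2PL with all discriminations 1 and
#'   intercepts 0, `J` in \{3..7, 10\} x `N` in \{250, 500, 1000\},
#'   continuity on. Type I error under monotone homogeneity.
#' * `"dim1-random"`: `n_cases` unidimensional parameter cases drawn once
#'   per case: `J` uniform on \{3..30\}, `N` uniform on \[250, 2500\],
#'   per-item discriminations uniform on \[0.5, 2\] and intercepts uniform
#'   on \[-1, 1\], continuity on.
#' * `"dim2-power"`: two-dimensional model with loading discriminations
#'   1.7, intercepts 0, `J` in \{10, 20, 30\}, `N` = 500, continuity off.
#'   Power study.
#'
#' @param name Preset name.
#' @param n_reps Replications per design cell.
#' @param n_cases Number of random parameter cases (`"dim1-random"` only).
#' @param seed Seed for drawing the random parameter cases
#'   (`"dim1-random"` only; the replication randomness is seeded by
#'   [run_rejection_grid()]).
#' @return A named list of [sim_design()] objects.
#' @export
#' @examples
#' length(preset_designs("dim0-small", n_reps = 10)) # 6 cells
preset_designs <- function(name = c("dim0-small", "dim1-grid",
                                    "dim1-random", "dim2-power"),
                           n_reps = 100, n_cases = 20, seed = NULL) {
  name <- match.arg(name)
  out <- list()
  switch(
    name,
    "dim0-small" = {
      for (J in c(3, 4, 5)) for (N in c(250, 500)) {
        out[[sprintf("dim0 J=%d N=%d", J, N)]] <-
          sim_design(J = J, N = N, scenario = "dim0", a = 0, b = 0,
                     n_reps = n_reps, continuity = TRUE)
      }
    },
    "dim1-grid" = {
      for (J in c(3:7, 10)) for (N in c(250, 500, 1000)) {
        out[[sprintf("dim1 J=%d N=%d", J, N)]] <-
          sim_design(J = J, N = N, scenario = "dim1", a = 1, b = 0,
                     n_reps = n_reps, continuity = TRUE)
      }
    },
    "dim1-random" = {
      case_seeds <- spawn_seeds(seed, n_cases)
      for (i in seq_len(n_cases)) {
        des <- with_seed(case_seeds[i], {
          J <- sample(3:30, 1)
          N <- round(runif(1, 250, 2500))
          sim_design(J = J, N = N, scenario = "dim1",
                     a = runif(J, 0.5, 2), b = runif(J, -1, 1),
                     n_reps = n_reps, continuity = TRUE)
        })
        out[[sprintf("case%02d J=%d N=%d", i, des$J, des$N)]] <- des
      }
    },
    "dim2-power" = {
      for (J in c(10, 20, 30)) {
        out[[sprintf("dim2 J=%d N=500", J)]] <-
          sim_design(J = J, N = 500, scenario = "dim2", a = 1.7, b = 0,
                     n_reps = n_reps, continuity = FALSE)
      }
    }
  )
  out
}
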