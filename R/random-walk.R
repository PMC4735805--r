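# Lattice random-walk simulation of a diffusing regulator (e.g. calmodulin)
# binding immobilized channel clusters, with a dissociation-constant (Kd)
# readout. Defaults reproduce the reference geometry: 33 nm lattice step
# (the estimated pore-to-pore channel spacing), a 1,066 nm square footprint
# (the measured mean centroid-to-centroid cluster distance, 32 steps),
# height 16 steps, 2,127 ligates (6 uM in the cuboid volume) and 44 surface
# channels, walked for 500 steps.

AVOGADRO <- 6.02214076e23

#' Random-walk binding configuration
#'
#' @param step_nm Lattice step (nm; default 33).
#' @param nx,ny,nz Lattice extent in steps (defaults 32, 32, 16; 32 =
#'   `round(1066 / 33)`).
#' @param n_ligate Number of diffusing ligates (default 2127, the count a
#'   6 uM concentration yields in the default cuboid; see
#'   [ligates_from_concentration()]).
#' @param n_channels Number of immobilized channels on the z = 0 face
#'   (default 44).
#' @param arrangement `"clustered"` (compact patch at 1-site pitch centered
#'   on the face) or `"distributed"` (uniform grid over the face).
#' @param p_bind Probability that a ligate standing on a free channel site
#'   binds, per step.
#' @param p_unbind Probability that a bound ligate dissociates, per step.
#' @param attraction Factor (`>= 1`) multiplying the weight of a move onto
#'   an adjacent unbound channel site.
#' @param exclusion Site-exclusion rule. `FALSE` (default): ligates are
#'   volumeless, any number may share a site, a bound channel site is
#'   passable without attraction, and a channel binds at most one ligate.
#'   `TRUE`: a channel site additionally holds at most one ligate (standing
#'   or bound) and occupied channel sites are impassable. The default
#'   reproduces the qualitative clustered-vs-distributed Kd ordering; see
#'   the methods vignette.
#' @param n_steps Steps per run (default 500).
#' @param n_reps Repetitions for replicate averaging (default 1000).
#' @param from_concentration_uM If given, overrides `n_ligate` with the
#'   count implied by this molar concentration in the lattice volume.
#' @param seed Integer seed.
#' @return A `walk_config`.
#' @export
walk_config <- function(step_nm = 33, nx = 32, ny = 32, nz = 16,
                        n_ligate = 2127, n_channels = 44,
                        arrangement = c("clustered", "distributed"),
                        p_bind = 0.5, p_unbind = 0.002, attraction = 1,
                        n_steps = 500, n_reps = 1000,
                        from_concentration_uM = NULL, exclusion = FALSE,
                        seed = NULL) {
  arrangement <- match.arg(arrangement)
  if (!is.null(from_concentration_uM)) {
    n_ligate <- ligates_from_concentration(from_concentration_uM,
                                           step_nm, nx, ny, nz)
  }
  stopifnot(p_bind >= 0, p_bind <= 1, p_unbind >= 0, p_unbind <= 1,
            attraction >= 1, n_steps >= 1, n_reps >= 1,
            nx >= 1, ny >= 1, nz >= 2, n_channels >= 0, n_ligate >= 1)
  if (n_channels > nx * ny) abort("more channels than face sites")
  structure(list(step_nm = step_nm, nx = nx, ny = ny, nz = nz,
                 n_ligate = n_ligate, n_channels = n_channels,
                 arrangement = arrangement, p_bind = p_bind,
                 p_unbind = p_unbind, attraction = attraction,
                 n_steps = n_steps, n_reps = n_reps,
                 exclusion = isTRUE(exclusion), seed = seed),
            class = "walk_config")
}

#' Lattice volume in liters
#' @param config A [walk_config()].
#' @return Volume of the cuboid `(nx * step) x (ny * step) x (nz * step)`
#'   in liters.
#' @export
walk_volume_L <- function(config) {
  v_nm3 <- (config$nx * config$step_nm) * (config$ny * config$step_nm) *
    (config$nz * config$step_nm)
  v_nm3 * 1e-24
}

#' Ligate count implied by a molar concentration
#'
#' `round(c * N_A * V)` with V the lattice cuboid volume. At the default
#' geometry, 6 uM gives 2,127 molecules.
#'
#' @param conc_uM Concentration in micromolar.
#' @param step_nm,nx,ny,nz Lattice geometry.
#' @return Integer molecule count.
#' @export
ligates_from_concentration <- function(conc_uM, step_nm = 33, nx = 32,
                                       ny = 32, nz = 16) {
  v_L <- (nx * step_nm) * (ny * step_nm) * (nz * step_nm) * 1e-24
  round(conc_uM * 1e-6 * AVOGADRO * v_L)
}

# channel (x, y) sites on the z = 0 face, 0-based
channel_layout <- function(config) {
  k <- config$n_channels
  nx <- config$nx; ny <- config$ny
  if (k == 0) return(matrix(integer(0), 0, 2))
  if (config$arrangement == "clustered") {
    side <- ceiling(sqrt(k))
    x0 <- floor((nx - side) / 2); y0 <- floor((ny - side) / 2)
    g <- expand.grid(x = x0 + seq_len(side) - 1, y = y0 + seq_len(side) - 1)
    g <- g[order(abs(g$x - (nx - 1) / 2) + abs(g$y - (ny - 1) / 2)), ]
    as.matrix(g[seq_len(k), ])
  } else {
    side <- ceiling(sqrt(k))
    pos <- round(seq(0, nx - 1, length.out = side))
    posy <- round(seq(0, ny - 1, length.out = side))
    g <- expand.grid(x = pos, y = posy)
    # keep the k grid sites closest to the face center
    g <- g[order((g$x - (nx - 1) / 2)^2 + (g$y - (ny - 1) / 2)^2), ]
    as.matrix(g[seq_len(k), ])
  }
}

#' Initialize a walk state
#'
#' Channels are laid out on the z = 0 face per the configured arrangement;
#' ligates are placed uniformly over all non-channel lattice sites (several
#' ligates may share a site; channel sites hold at most one).
#'
#' @param config A [walk_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return A `walk_state`: list with `ligate` (n x 3 matrix of 0-based
#'   lattice coords), `bound` (per-ligate 0-based channel index or -1),
#'   `channels` (k x 2), `step` (0), and the config.
#' @export
init_state <- function(config, seed = config$seed) {
  ch <- channel_layout(config)
  if (nrow(ch) != config$n_channels) abort("channel layout failed")
  with_seed(seed, {
    nsite <- config$nx * config$ny * config$nz
    chan_lin <- if (nrow(ch)) ch[, 1] + config$nx * ch[, 2] else integer(0)
    ok <- setdiff(seq_len(nsite) - 1L,
                  chan_lin)  # z = 0 channel sites excluded
    s <- sample(ok, config$n_ligate, replace = TRUE)
    z <- s %/% (config$nx * config$ny)
    r <- s %% (config$nx * config$ny)
    lig <- cbind(x = r %% config$nx, y = r %/% config$nx, z = z)
    structure(list(ligate = lig, bound = rep(-1L, config$n_ligate),
                   channels = ch, step = 0L, config = config),
              class = "walk_state")
  })
}

#' Advance a walk state
#'
#' Runs the compiled engine for `n_steps` steps starting from `state`.
#' Draws from R's RNG stream, so wrap in `set.seed()` (or use [run_walk()])
#' for reproducibility.
#'
#' @param state A `walk_state`.
#' @param n_steps Number of steps to advance (default 1).
#' @return The advanced `walk_state`, with the per-step bound-channel count
#'   appended to `bound_trace`.
#' @export
step_walk <- function(state, n_steps = 1) {
  cfg <- state$config
  res <- walk_engine_cpp(state$ligate, as.integer(state$bound),
                         state$channels,
                         cfg$nx, cfg$ny, cfg$nz, as.integer(n_steps),
                         cfg$p_bind, cfg$p_unbind, cfg$attraction,
                         cfg$exclusion %||% FALSE)
  state$ligate <- res$positions
  state$bound <- res$bound_channel
  state$bound_trace <- c(state$bound_trace, res$bound_trace)
  state$step <- state$step + n_steps
  state
}

#' Run one complete walk
#'
#' @param config A [walk_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return A `walk_trace`: list with `bound_trace` (bound-channel count at
#'   each step), the final `state`, and the config.
#' @export
run_walk <- function(config, seed = config$seed) {
  state <- init_state(config, seed = seed)
  state <- with_seed(derive_seed(seed, 1) %||% NULL, {
    step_walk(state, config$n_steps)
  })
  structure(list(bound_trace = state$bound_trace, state = state,
                 config = config),
            class = "walk_trace")
}

#' Estimate the dissociation constant from a walk trace
#'
#' `Kd = [free ligate] * (free channels) / (bound channels)` with the free
#' ligate concentration computed from counts over the lattice cuboid
#' volume, averaged over the equilibration window (by default the last 40%
#' of steps). Reported in nM. A stationarity check compares the two halves
#' of the window and warns when their means differ by more than 3 standard
#' errors.
#'
#' @param trace A `walk_trace` (or a `walk_config` plus `bound_trace`
#'   vector).
#' @param window Fraction of trailing steps used (default 0.4).
#' @param check_stationarity Warn when the window looks unconverged.
#' @return A `kd_estimate`: list with `kd_nM`, `infinite` flag,
#'   `bound_fraction` (mean over window), `window_steps`, `free_conc_nM`.
#' @export
estimate_kd <- function(trace, window = 0.4, check_stationarity = FALSE) {
  cfg <- trace$config
  bt <- trace$bound_trace
  n_steps <- length(bt)
  w0 <- n_steps - floor(window * n_steps) + 1
  win <- bt[w0:n_steps]
  mean_bound <- mean(win)
  mean_free_ch <- cfg$n_channels - mean_bound
  mean_free_lig <- cfg$n_ligate - mean_bound
  v_L <- walk_volume_L(cfg)
  free_conc_nM <- mean_free_lig / (AVOGADRO * v_L) * 1e9
  if (check_stationarity) {
    h <- length(win) %/% 2
    a <- win[seq_len(h)]; b <- win[(h + 1):length(win)]
    se <- sqrt(sd(a)^2 / h + sd(b)^2 / (length(win) - h))
    if (is.finite(se) && se > 0 && abs(mean(a) - mean(b)) > 3 * se) {
      warn("bound-count trace may not be stationary over the Kd window")
    }
  }
  infinite <- mean_bound == 0
  kd <- if (infinite) Inf else free_conc_nM * mean_free_ch / mean_bound
  structure(list(kd_nM = kd, infinite = infinite,
                 bound_fraction = mean_bound / max(cfg$n_channels, 1),
                 window_steps = c(w0, n_steps),
                 free_conc_nM = free_conc_nM, config = cfg),
            class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("Kd estimate: %s nM (bound fraction %.3f, window steps %d-%d)\n",
              if (x$infinite) "Inf" else sprintf("%.1f", x$kd_nM),
              x$bound_fraction, x$window_steps[1], x$window_steps[2]))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.kd_estimate <- function(x, ...) {
  tibble(kd_nM = x$kd_nM, infinite = x$infinite,
         bound_fraction = x$bound_fraction,
         free_conc_nM = x$free_conc_nM)
}

#' Replicate Kd estimates
#'
#' Runs `n_reps` independent walks (sub-seeded from `seed`) and estimates
#' Kd for each.
#'
#' @param config A [walk_config()].
#' @param n_reps Number of repetitions (defaults to the config's).
#' @param seed Base seed (defaults to the config's).
#' @param window Equilibration window fraction.
#' @return Tibble with `rep`, `kd_nM`, `bound_fraction`.
#' @export
run_walk_reps <- function(config, n_reps = config$n_reps,
                          seed = config$seed, window = 0.4) {
  out <- purrr::map(seq_len(n_reps), function(r) {
    tr <- run_walk(config, seed = derive_seed(seed, r))
    kd <- estimate_kd(tr, window = window)
    tibble(rep = r, kd_nM = kd$kd_nM, bound_fraction = kd$bound_fraction)
  })
  dplyr::bind_rows(out)
}

#' Calibrate binding probabilities toward a target Kd
#'
#' Runs replicate-averaged Kd for every `(p_bind, p_unbind)` grid point and
#' tabulates the distance to the target. Points within `tol_frac` of the
#' target are flagged calibrated.
#'
#' @param target_kd_nM Target dissociation constant (nM); e.g. 110, the
#'   mean of the 88 nM (apo) and 132 nM (Ca2+-bound) calmodulin anchors.
#' @param p_bind_grid,p_unbind_grid Probability grids.
#' @param config Base [walk_config()] (its `p_bind`/`p_unbind` are
#'   overridden).
#' @param n_reps Repetitions per grid point.
#' @param seed Base seed.
#' @param tol_frac Relative tolerance for the calibrated flag.
#' @return Tibble sorted by `abs_error_nM`: `p_bind`, `p_unbind`, `kd_nM`,
#'   `abs_error_nM`, `infinite`, `calibrated`.
#' @export
calibrate_probabilities <- function(target_kd_nM, p_bind_grid, p_unbind_grid,
                                    config, n_reps = 20,
                                    seed = config$seed, tol_frac = 0.25) {
  grid <- expand.grid(p_bind = p_bind_grid, p_unbind = p_unbind_grid)
  if (nrow(grid) == 0) abort("empty probability grid")
  out <- purrr::map(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg$p_bind <- grid$p_bind[g]
    cfg$p_unbind <- grid$p_unbind[g]
    reps <- run_walk_reps(cfg, n_reps = n_reps,
                          seed = derive_seed(seed, 1000 + g))
    kd <- mean(reps$kd_nM)
    tibble(p_bind = cfg$p_bind, p_unbind = cfg$p_unbind, kd_nM = kd,
           infinite = !is.finite(kd))
  })
  res <- dplyr::bind_rows(out)
  if (all(res$infinite)) {
    warn("calibration failure: every grid point produced an infinite Kd")
  }
  res$abs_error_nM <- abs(res$kd_nM - target_kd_nM)
  res$calibrated <- is.finite(res$kd_nM) &
    res$abs_error_nM <= tol_frac * target_kd_nM
  dplyr::arrange(res, .data$abs_error_nM)
}

#' Compare clustered and distributed channel arrangements
#'
#' Paired replicate Kd estimates for the two arrangements using common
#' random seeds per repetition, a one-sided Wilcoxon signed-rank test of
#' Kd(clustered) < Kd(distributed), and summary statistics.
#'
#' @param config Base [walk_config()] (calibrated `p_bind`/`p_unbind` and
#'   `attraction` set).
#' @param n_reps Paired repetitions.
#' @param seed Base seed.
#' @return An `arrangement_comparison`: list with `per_rep` (tibble: rep,
#'   kd_clustered, kd_distributed), `summary` tibble, `p_value`, and the
#'   config.
#' @export
compare_arrangements <- function(config, n_reps = config$n_reps,
                                 seed = config$seed) {
  cfg_c <- config; cfg_c$arrangement <- "clustered"
  cfg_d <- config; cfg_d$arrangement <- "distributed"
  kc <- run_walk_reps(cfg_c, n_reps = n_reps, seed = seed)
  kd <- run_walk_reps(cfg_d, n_reps = n_reps, seed = seed)
  per_rep <- tibble(rep = kc$rep, kd_clustered = kc$kd_nM,
                    kd_distributed = kd$kd_nM)
  fin <- is.finite(per_rep$kd_clustered) & is.finite(per_rep$kd_distributed)
  pv <- tryCatch(
    wilcox.test(per_rep$kd_clustered[fin], per_rep$kd_distributed[fin],
                paired = TRUE, alternative = "less", exact = FALSE)$p.value,
    error = function(e) NA_real_)
  smry <- tibble(
    arrangement = c("clustered", "distributed"),
    kd_mean_nM = c(mean(per_rep$kd_clustered[fin]),
                   mean(per_rep$kd_distributed[fin])),
    kd_sd_nM = c(sd(per_rep$kd_clustered[fin]),
                 sd(per_rep$kd_distributed[fin])))
  structure(list(per_rep = per_rep, summary = smry, p_value = pv,
                 config = config),
            class = "arrangement_comparison")
}

#' @export
print.arrangement_comparison <- function(x, ...) {
  cat(sprintf(
    "clustered vs distributed (n = %d paired reps): Kd %.1f vs %.1f nM, one-sided p = %.3g\n",
    nrow(x$per_rep), x$summary$kd_mean_nM[1], x$summary$kd_mean_nM[2],
    x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.arrangement_comparison <- function(x, ...) x$per_rep

#' @exportS3Method generics::glance
glance.arrangement_comparison <- function(x, ...) {
  tibble(kd_clustered_nM = x$summary$kd_mean_nM[1],
         kd_distributed_nM = x$summary$kd_mean_nM[2],
         p_value = x$p_value, n_reps = nrow(x$per_rep))
}
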