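#' Thresholds for trajectory classification
#'
#' All cut-offs of the geometric trajectory classifier in one place. The five
#' trajectory modes are qualitative; committed, configurable thresholds make
#' the classification reproducible. Defaults were calibrated once on the
#' package's reference fixture so that the archetypal geometries survive the
#' smoothing noise of profiles built from fewer than a hundred cells (see the
#' methods vignette).
#'
#' @param r_anti Pearson correlation at or below which two curves count as
#'   anti-correlated (default -0.8).
#' @param r_orth Absolute correlation at or below which curves count as
#'   uncorrelated (default 0.3).
#' @param lead_complete,lag_complete Range-completion fractions of the strict
#'   switch-like rule: one axis completes `lead_complete` (default 0.8) of
#'   its range before the other completes `lag_complete` (default 0.2).
#' @param lead_sep Minimal separation of the two axes' half-range crossing
#'   times (as a fraction of the pseudotime range) for the relaxed
#'   switch-like rule, which requires both axes to travel in the same net
#'   direction (default 0.15).
#' @param straight_max Bow (maximum perpendicular deviation from the
#'   endpoint chord, normalized by chord length) above which a curve counts
#'   as visibly bent, triggering the `curved` label (default 0.45).
#' @param const_band Maximal span of an axis (on the \[0, 1\] relative scale)
#'   for it to count as near-constant (default 0.3).
#' @param corner_sep Minimal per-axis separation of two branches' terminal
#'   states, in opposite directions, for the divergent call (default 0.4).
#' @param min_range Minimal range an axis must traverse for the completion
#'   rules to apply to it (default 0.3).
#' @param min_net Minimal net displacement, as a fraction of the axis range,
#'   for the axis to count as directional rather than transient (default
#'   0.1).
#' @param n_grid Number of uniform pseudotime grid points used to resample
#'   curves (default 101).
#' @return A named list of thresholds.
#' @export
typology_control <- function(r_anti = -0.8, r_orth = 0.3,
                             lead_complete = 0.8, lag_complete = 0.2,
                             lead_sep = 0.15, straight_max = 0.45,
                             const_band = 0.3, corner_sep = 0.4,
                             min_range = 0.3, min_net = 0.1, n_grid = 101L) {
  list(r_anti = r_anti, r_orth = r_orth,
       lead_complete = lead_complete, lag_complete = lag_complete,
       lead_sep = lead_sep, straight_max = straight_max,
       const_band = const_band, corner_sep = corner_sep,
       min_range = min_range, min_net = min_net, n_grid = as.integer(n_grid))
}

# Resample a trajectory_pair onto a uniform pseudotime grid.
resample_pair <- function(pair, n_grid) {
  assert_that(all(c("pt", "a", "b") %in% names(pair)), "`pair` needs columns pt, a, b")
  assert_that(nrow(pair) >= 10L, "trajectory needs at least 10 curve points")
  pair <- dplyr::arrange(tibble::as_tibble(pair), .data$pt)
  grid <- seq(min(pair$pt), max(pair$pt), length.out = n_grid)
  list(
    t = grid,
    a = stats::approx(pair$pt, pair$a, xout = grid, ties = mean)$y,
    b = stats::approx(pair$pt, pair$b, xout = grid, ties = mean)$y,
    # the curve's own support: correlation is estimated here, where the
    # smooths are defined, not on the interpolated grid
    a_obs = pair$a, b_obs = pair$b
  )
}

# Geometric statistics of one resampled curve. `kappa` is the classical
# path-based curvature index 1 - chord/path (it also counts backtracking);
# `bow` is the maximum perpendicular deviation from the endpoint chord
# normalized by chord length (insensitive to backtracking along the chord,
# hence the decision statistic for straight vs bent).
trajectory_stats <- function(rs) {
  n <- length(rs$a)
  da <- diff(rs$a); db <- diff(rs$b); dt <- diff(rs$t)
  speed <- sqrt(da^2 + db^2)
  path <- sum(speed)
  chord <- sqrt((rs$a[n] - rs$a[1L])^2 + (rs$b[n] - rs$b[1L])^2)
  kappa <- if (path > 0) 1 - chord / path else 0
  bow <- if (chord > 0) {
    v <- c(rs$a[n] - rs$a[1L], rs$b[n] - rs$b[1L]) / chord
    max(abs((rs$a - rs$a[1L]) * v[2L] - (rs$b - rs$b[1L]) * v[1L])) / chord
  } else {
    Inf
  }
  ra <- rs$a_obs %||% rs$a
  rb <- rs$b_obs %||% rs$b
  r <- if (stats::sd(ra) > 0 && stats::sd(rb) > 0) stats::cor(ra, rb) else 0
  # lag: derivative cross-correlation over shifts up to 40% of the PT range
  max_shift <- max(1L, floor(0.4 * (n - 1L)))
  shifts <- seq.int(-max_shift, max_shift)
  cc <- vapply(shifts, function(s) {
    if (s >= 0) {
      ia <- seq_len(n - 1L - s); ib <- ia + s
    } else {
      ib <- seq_len(n - 1L + s); ia <- ib - s
    }
    if (stats::sd(da[ia]) == 0 || stats::sd(db[ib]) == 0) return(NA_real_)
    stats::cor(da[ia], db[ib])
  }, numeric(1L))
  lag <- if (all(is.na(cc))) 0 else shifts[which.max(cc)] * mean(dt)
  plateau <- if (max(speed) > 0) mean(speed < 0.1 * max(speed)) else 1
  list(r = r, lag = lag, kappa = kappa, bow = bow, plateau = plateau)
}

# Per-axis motion summary: span, net direction and the first times the axis
# completes fractions of its range (in the direction of net travel). An axis
# with span below `min_range`, or with net displacement below `min_net` of
# its span (non-monotone excursion), is not "directional": its completion
# times are NA.
axis_motion <- function(t, v, ctl) {
  rng <- range(v); span <- rng[2L] - rng[1L]
  net <- v[length(v)] - v[1L]
  directional <- span >= ctl$min_range && abs(net) >= ctl$min_net * span
  cross <- function(q) {
    if (!directional) return(NA_real_)
    prog <- if (net > 0) (v - rng[1L]) / span else (rng[2L] - v) / span
    idx <- which(prog >= q)
    if (length(idx) == 0L) NA_real_ else t[idx[1L]]
  }
  list(span = span, net = net, directional = directional,
       t_lag = cross(ctl$lag_complete), t_half = cross(0.5),
       t_lead = cross(ctl$lead_complete))
}

# TRUE if one axis stays within a narrow band while the other is active.
one_axis_constant <- function(rs, ctl) {
  near_const <- function(mover, still) {
    dm <- abs(diff(mover))
    if (max(dm) == 0) return(FALSE)
    active <- which(dm > 0.2 * max(dm))
    if (length(active) == 0L) return(FALSE)
    win <- range(still[c(active, active + 1L)])
    (win[2L] - win[1L]) <= ctl$const_band
  }
  near_const(rs$a, rs$b) || near_const(rs$b, rs$a)
}

classify_single <- function(rs, ctl) {
  st <- trajectory_stats(rs)
  ma <- axis_motion(rs$t, rs$a, ctl)
  mb <- axis_motion(rs$t, rs$b, ctl)
  t_span <- diff(range(rs$t))

  # strict switch rule: one axis completes most of its range before the
  # other starts moving
  strict_ab <- !is.na(ma$t_lead) && !is.na(mb$t_lag) && ma$t_lead <= mb$t_lag
  strict_ba <- !is.na(mb$t_lead) && !is.na(ma$t_lag) && mb$t_lead <= ma$t_lag
  # relaxed switch rule: both axes travel the same way but their half-range
  # crossings are well separated in pseudotime (sequential activation)
  same_dir <- ma$directional && mb$directional && sign(ma$net) == sign(mb$net)
  sep <- if (same_dir && !is.na(ma$t_half) && !is.na(mb$t_half)) {
    (mb$t_half - ma$t_half) / t_span
  } else {
    0
  }
  relaxed_ab <- same_dir && sep >= ctl$lead_sep
  relaxed_ba <- same_dir && -sep >= ctl$lead_sep

  # strongly anti-correlated axes are never "sequential activation":
  # they belong to the parallel/divergent family
  anti <- st$r <= ctl$r_anti
  leading <- NA_character_
  label <- if (!anti && (strict_ab || strict_ba || relaxed_ab || relaxed_ba)) {
    leading <- if (strict_ab || relaxed_ab) "a" else "b"
    "switch_like"
  } else if (st$r <= ctl$r_anti) {
    # r <= -0.8 already confines the point cloud to an aspect ratio of about
    # 1/3 around a falling line, so no separate straightness test is needed
    "parallel_anticorrelated"
  } else if (abs(st$r) <= ctl$r_orth && one_axis_constant(rs, ctl)) {
    "orthogonal"
  } else if (st$bow > ctl$straight_max) {
    "curved"
  } else {
    "unclassified"
  }
  c(st, list(label = label, leading = leading))
}

# Terminal state of a branch: mean over the last decile of grid points,
# which is more stable than the single endpoint of a smoothed curve.
terminal_state <- function(rs) {
  n <- length(rs$a)
  tail_idx <- seq.int(max(1L, n - floor(n / 10)), n)
  c(a = mean(rs$a[tail_idx]), b = mean(rs$b[tail_idx]))
}

#' Classify the geometry of a biaxial signature trajectory
#'
#' Applies fixed-order decision rules on the geometric statistics of a
#' relative-activity trajectory (both axes in \[0, 1\]):
#'
#' 1. `switch_like` — one axis completes its range before the other starts
#'    (strict 80/20 completion ordering), or both axes move in the same net
#'    direction with well-separated half-range crossing times (sequential
#'    activation, e.g. oxphos saturating before proliferation takes over);
#' 2. `parallel_anticorrelated` — strongly anti-correlated and not visibly
#'    bent: a straight anti-diagonal (e.g. poised vs active promoter
#'    activity);
#' 3. `divergent` — only for multi-branch input (a list of trajectories, one
#'    per culture/branch): strongly anti-correlated axes whose branch
#'    terminal states separate into opposite corners (e.g. MITF-high/AXL-low
#'    vs MITF-low/AXL-high endpoints across cultures). A single branch cannot
#'    distinguish divergence from a plain anti-diagonal and collapses to
#'    `parallel_anticorrelated`;
#' 4. `orthogonal` — uncorrelated, one axis near-constant while the other
#'    moves;
#' 5. `curved` — visibly bent (large bow) but none of the above;
#' 6. `unclassified` otherwise.
#'
#' For multi-branch input the divergent check runs first (each branch of a
#' divergent pair is itself a straight anti-diagonal, which would otherwise
#' always be caught by rule 2); if it fails, branches are classified
#' individually and a unanimous label is reported, else `unclassified`.
#'
#' @param pair A `trajectory_pair` (see [biaxial_trajectory()]) or a list of
#'   them (one per branch/culture) for the multi-branch rules.
#' @param control Thresholds from [typology_control()].
#' @return A one-row `typology_call` tibble: `set_a`, `set_b`, `label`, `r`,
#'   `lag`, `curvature` (path-based index, 1 - chord/path), `bow`
#'   (chord-deviation index), `plateau_fraction`, `leading_axis`,
#'   `n_branches`.
#' @export
classify_trajectory <- function(pair, control = typology_control()) {
  ctl <- control
  multi <- is.list(pair) && !is.data.frame(pair)
  pairs <- if (multi) pair else list(pair)
  assert_that(length(pairs) >= 1L, "`pair` must contain at least one trajectory")
  rs <- lapply(pairs, resample_pair, n_grid = ctl$n_grid)
  calls <- lapply(rs, classify_single, ctl = ctl)
  set_a <- attr(pairs[[1L]], "set_a") %||% "a"
  set_b <- attr(pairs[[1L]], "set_b") %||% "b"

  mean_r <- mean(vapply(calls, `[[`, numeric(1L), "r"))
  label <- NA_character_
  if (multi && length(rs) >= 2L && mean_r <= ctl$r_anti) {
    ends <- t(vapply(rs, terminal_state, numeric(2L)))
    # branches i, j diverge when i ends a-high/b-low and j ends a-low/b-high
    for (i in seq_len(nrow(ends))) {
      for (j in seq_len(nrow(ends))) {
        if (i != j &&
            ends[i, "a"] - ends[j, "a"] >= ctl$corner_sep &&
            ends[j, "b"] - ends[i, "b"] >= ctl$corner_sep) {
          label <- "divergent"
        }
      }
    }
  }
  if (is.na(label)) {
    labels <- vapply(calls, `[[`, character(1L), "label")
    label <- if (length(unique(labels)) == 1L) labels[[1L]] else "unclassified"
  }
  leading <- vapply(calls, `[[`, character(1L), "leading")
  leading <- if (all(is.na(leading))) NA_character_ else stats::na.omit(leading)[1L]
  out <- tibble::tibble(
    set_a = set_a, set_b = set_b, label = label,
    r = mean_r,
    lag = mean(vapply(calls, `[[`, numeric(1L), "lag")),
    curvature = mean(vapply(calls, `[[`, numeric(1L), "kappa")),
    bow = mean(vapply(calls, `[[`, numeric(1L), "bow")),
    plateau_fraction = mean(vapply(calls, `[[`, numeric(1L), "plateau")),
    leading_axis = leading,
    n_branches = length(rs)
  )
  class(out) <- c("typology_call", class(out))
  out
}

#' Classify several signature pairs at once
#'
#' @param profiles A long `signature_profile` tibble with a `relative`
#'   column (see [profile_signatures()]), or a named list of such tibbles
#'   (one per branch/culture).
#' @param pairs A two-column data frame or list of 2-vectors naming the
#'   signature pairs to classify.
#' @param control Thresholds from [typology_control()].
#' @return A `typology_call` tibble, one row per pair.
#' @export
classify_pairs <- function(profiles, pairs, control = typology_control()) {
  branches <- if (is.data.frame(profiles)) list(profiles) else profiles
  if (is.data.frame(pairs)) pairs <- purrr::transpose(pairs) %>% purrr::map(unlist)
  purrr::map(pairs, function(p) {
    traj <- purrr::map(branches, function(br) {
      biaxial_trajectory(dplyr::filter(br, .data$set == p[[1L]]),
                         dplyr::filter(br, .data$set == p[[2L]]))
    })
    classify_trajectory(if (length(traj) == 1L) traj[[1L]] else traj, control = control)
  }) %>%
    dplyr::bind_rows()
}
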