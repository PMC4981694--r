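#' Diet totals and macronutrient energy percentages
#'
#' Given a serving prescription (servings/day per food group) and a food
#' table, accumulates grams of carbohydrate, protein and fat, converts to
#' energy with the 17/17/36 kJ/g factors, and expresses each
#' macronutrient's energy contribution as a percentage of total energy.
#' The three percentages always close to 100 for any non-empty diet.
#'
#' @param servings named numeric vector: servings/day keyed by `group_id`.
#'   All values must be >= 0.
#' @param table a [food_table()] containing every named group.
#' @return object of class `diet_totals`: grams per macronutrient, total
#'   energy (kJ/day), percentage vector `pct` (`cho`, `ptn`, `fat`) and a
#'   `defined` flag (`FALSE` for a zero-energy diet, whose percentages are
#'   undefined rather than an error).
#' @examples
#' tab <- food_table(data.frame(group_id = "g", name = "g",
#'                              serving_size_g = 40, cho_g = 15,
#'                              ptn_g = 5, fat_g = 2))
#' diet_totals(c(g = 2), tab)
#' @export
diet_totals <- function(servings, table) {
  stopifnot(is.numeric(servings))
  if (length(servings) > 0 && is.null(names(servings))) {
    stop("servings must be named by group_id", call. = FALSE)
  }
  unknown <- setdiff(names(servings), table$group_id)
  if (length(unknown) > 0) {
    stop("unknown group(s) in prescription: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(servings < 0)) stop("servings must be >= 0", call. = FALSE)
  idx <- match(names(servings), table$group_id)
  g <- c(cho = sum(servings * table$cho_g[idx]),
         ptn = sum(servings * table$ptn_g[idx]),
         fat = sum(servings * table$fat_g[idx]))
  energy <- sum(KJ_PER_G * g)
  defined <- energy > 0
  pct <- if (defined) KJ_PER_G * g / energy * 100 else
    stats::setNames(rep(NA_real_, 3), MACROS)
  structure(list(total_cho_g = unname(g["cho"]),
                 total_ptn_g = unname(g["ptn"]),
                 total_fat_g = unname(g["fat"]),
                 total_energy_kj = energy,
                 pct = pct,
                 defined = defined),
            class = "diet_totals")
}

#' @export
print.diet_totals <- function(x, ...) {
  cat(sprintf("Diet totals: CHO %.2f g, PTN %.2f g, FAT %.2f g; %.1f kJ\n",
              x$total_cho_g, x$total_ptn_g, x$total_fat_g,
              x$total_energy_kj))
  if (x$defined) {
    cat(sprintf("  energy split: %%CHO %.2f  %%PTN %.2f  %%FAT %.2f\n",
                x$pct["cho"], x$pct["ptn"], x$pct["fat"]))
  } else {
    cat("  energy split undefined (zero-energy diet)\n")
  }
  invisible(x)
}

#' Euclidean distance between achieved and target energy percentages
#'
#' d = sqrt((pctCHO - targetCHO)^2 + (pctPTN - targetPTN)^2 +
#' (pctFAT - targetFAT)^2), in percentage points. This is the objective
#' the serving solver minimizes.
#'
#' @param totals a [diet_totals()] with defined percentages.
#' @param targets numeric vector with `cho`, `ptn`, `fat` elements
#'   (percent), or a [study_config()].
#' @return distance in percentage points.
#' @export
macro_distance <- function(totals, targets) {
  if (inherits(targets, "study_config")) targets <- targets$targets
  targets <- unlist(targets)[MACROS]
  stopifnot(inherits(totals, "diet_totals"))
  if (!totals$defined) {
    stop("percentages undefined for a zero-energy diet", call. = FALSE)
  }
  sqrt(sum((totals$pct - targets)^2))
}

# Assemble the numeric pieces of the constrained problem: per-serving
# macro-gram matrix, per-serving energies, lower/upper serving bounds
# (strict printed maxima tightened by one increment), with groups in the
# table but absent from the constraint list left unconstrained above zero.
.problem_data <- function(cfg, table) {
  stopifnot(inherits(cfg, "study_config"), inherits(table, "food_table"))
  cons <- cfg$constraints
  unknown <- setdiff(cons$group_id, table$group_id)
  if (length(unknown) > 0) {
    stop("constraint group(s) not in food table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ids <- table$group_id
  n <- length(ids)
  idx <- match(ids, cons$group_id)
  lower <- ifelse(is.na(idx), 0, cons$min_servings[idx])
  upper <- ifelse(is.na(idx), Inf, cons$max_servings[idx])
  upper[is.na(upper)] <- Inf
  strict <- ifelse(is.na(idx), FALSE, cons$strict_max[idx])
  inc <- ifelse(is.na(idx), 0.5, cons$increment[idx])
  integral <- ifelse(is.na(idx), FALSE, cons$integral[idx])
  upper <- ifelse(strict & is.finite(upper), upper - inc, upper)
  if (any(upper < lower)) {
    bad <- ids[upper < lower][1]
    stop("effective upper bound below minimum for group ", bad,
         call. = FALSE)
  }
  A <- rbind(cho = table$cho_g, ptn = table$ptn_g, fat = table$fat_g)
  colnames(A) <- ids
  e <- as.numeric(KJ_PER_G %*% A)
  list(ids = ids, n = n, A = A, e = e, lower = lower, upper = upper,
       increment = inc, integral = integral,
       targets = cfg$targets)
}

# Squared-distance objective and its analytic gradient over the free
# coordinates, with fixed coordinates folded into constant gram/energy
# offsets. Working with d^2 keeps the gradient smooth at d = 0.
.objective_fns <- function(A, e, g0, e0, targets) {
  k <- KJ_PER_G
  f <- function(x) {
    g <- as.numeric(A %*% x) + g0
    E <- sum(e * x) + e0
    p <- 100 * k * g / E
    sum((p - targets)^2)
  }
  grad <- function(x) {
    g <- as.numeric(A %*% x) + g0
    E <- sum(e * x) + e0
    p <- 100 * k * g / E
    # dp_j/dx = 100 k_j (A_j E - g_j e) / E^2
    dp <- 100 * (k * (A * E - outer(g, e))) / E^2
    as.numeric(2 * (p - targets) %*% dp)
  }
  list(f = f, grad = grad)
}

# Secondary objective: among (near-)distance-minimal diets, maximize
# energy. Used when a serving maximum truncates the scaling ray short of
# the cap. Bisects on the energy level E: at each trial level the
# distance is minimized with the diet's energy softly pinned to E
# (quadratic penalty on the relative deviation); a level is achievable
# when the pinned minimum stays within d_tol of the unconstrained
# optimum d*.
.maximize_energy <- function(obj, e, eer_kj, x0, L, U, fstar, ui, ci,
                             d_tol = 1e-6) {
  fin <- is.finite(U)
  span <- ifelse(fin, pmax(U - L, 1e-3), 1)
  interiorize <- function(x) {
    x <- pmax(x, L + 1e-8 * span)
    x <- pmin(x, ifelse(fin, U - 1e-8 * span, x))
    if (sum(e * x) >= eer_kj) x <- x * (eer_kj * (1 - 1e-9) / sum(e * x))
    pmax(x, L + 1e-10)
  }
  w <- 1e4   # energy-pinning weight, (pct points)^2 per relative dev^2
  pinned_min <- function(E, xinit) {
    fE <- function(x) obj$f(x) + w * (sum(e * x) / E - 1)^2
    gE <- function(x) {
      obj$grad(x) + w * 2 * (sum(e * x) / E - 1) * e / E
    }
    tryCatch(
      stats::constrOptim(interiorize(xinit), f = fE, grad = gE, ui = ui,
                         ci = ci, method = "BFGS", outer.eps = 1e-9,
                         control = list(maxit = 200, reltol = 1e-14)),
      error = function(err) NULL)
  }
  d_ok <- (sqrt(fstar) + d_tol)^2
  e_lo <- sum(e * x0)
  xbest <- x0
  # try the cap outright before bisecting
  direct <- pinned_min(eer_kj, x0)
  if (!is.null(direct) && obj$f(direct$par) <= d_ok &&
      sum(e * direct$par) > e_lo) {
    return(direct$par)
  }
  lo <- e_lo
  hi <- eer_kj
  for (iter in 1:12) {
    mid <- (lo + hi) / 2
    res <- pinned_min(mid, xbest)
    if (!is.null(res) && obj$f(res$par) <= d_ok &&
        sum(e * res$par) > sum(e * xbest)) {
      xbest <- res$par
      lo <- mid
    } else {
      hi <- mid
    }
    if (hi - lo < 1e-4 * eer_kj) break
  }
  if (sqrt(obj$f(xbest)) <= sqrt(fstar) + d_tol &&
      sum(e * xbest) > e_lo) xbest else x0
}

# Largest feasible ray scale factor c >= 1 for x -> c x: percentages (and
# hence the distance) are invariant under scaling, so pushing the optimum
# out to the first binding constraint realises the energy-maximizing
# tie-break exactly.
.ray_scale <- function(x, e, upper, eer_kj) {
  energy <- sum(e * x)
  if (energy <= 0) return(1)
  c_energy <- eer_kj / energy
  active <- x > 0 & is.finite(upper)
  c_upper <- if (any(active)) min(upper[active] / x[active]) else Inf
  max(1, min(c_energy, c_upper))
}

#' Solve for the serving prescription
#'
#' Finds daily servings per food group minimizing the Euclidean distance
#' between achieved and target macronutrient energy percentages, subject
#' to the serving bounds (X_i >= T_i, and any maxima) and the energy cap
#' (total energy <= EER). Because percentages are scale-invariant, the
#' distance-minimal solution set typically contains whole rays; ties are
#' broken by maximizing total energy, so the prescription approaches the
#' participant's requirement from below rather than undershooting it.
#'
#' The solver runs multi-start projected minimization of the squared
#' distance (log-barrier interior method via [stats::constrOptim()] with
#' an analytic gradient) from the minima-anchored and energy-scaled random
#' starts, then applies the exact ray-scaling tie-break and a re-polish
#' pass. Deterministic for a fixed `seed`.
#'
#' @param cfg a [study_config()].
#' @param table a [food_table()]; its groups form the decision vector.
#' @param eer_kj participant energy requirement in kJ/day (the cap).
#' @param seed integer seed controlling the random restarts.
#' @param n_starts number of random restarts (in addition to deterministic
#'   starts).
#' @param tol convergence tolerance on the distance (percentage points).
#' @param round logical: also compute the grid-rounded prescription via
#'   [round_prescription()].
#' @return object of class `serving_solution`: `prescription` (named
#'   servings/day, continuous optimum), `rounded` (grid-snapped servings,
#'   when `round = TRUE`), `totals` and `totals_rounded`
#'   ([diet_totals()]), `distance`, `status` (`"optimal"`,
#'   `"infeasible"` or `"not_converged"`), `eer_kj` and `diagnostics`.
#' @examples
#' tab <- pure_macro_table()
#' cfg <- pure_macro_config()
#' sol <- solve_servings(cfg, tab, eer_kj = 3400, seed = 1)
#' sol$prescription  # c(10, 4, 5.667): exact 50/20/30 split at the cap
#' @export
solve_servings <- function(cfg, table, eer_kj, seed = 1L, n_starts = 10L,
                           tol = 1e-6, round = TRUE) {
  if (!is.finite(eer_kj) || eer_kj <= 0) {
    stop("eer_kj must be > 0", call. = FALSE)
  }
  pd <- .problem_data(cfg, table)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(seed)

  min_energy <- sum(pd$e * pd$lower)
  if (min_energy > eer_kj) {
    return(structure(list(
      prescription = stats::setNames(pd$lower, pd$ids),
      rounded = NULL, totals = NULL, totals_rounded = NULL,
      distance = NA_real_, status = "infeasible",
      infeasible_margin_kj = min_energy - eer_kj,
      eer_kj = eer_kj,
      diagnostics = list(note = "serving minima alone exceed the energy cap")),
      class = "serving_solution"))
  }
  if (sum(pd$e) == 0) {
    stop("food table delivers no energy; cannot form percentages",
         call. = FALSE)
  }
  if (eer_kj - min_energy <= 1e-9 * eer_kj) {
    # the cap pins every serving at its minimum
    x <- stats::setNames(pd$lower, pd$ids)
    tot <- diet_totals(x, table)
    d <- if (tot$defined) macro_distance(tot, cfg$targets) else NA_real_
    return(.finish_solution(x, tot, d, "optimal", cfg, table, eer_kj,
                            list(note = "energy cap binds at the minima"),
                            round))
  }

  fixed <- pd$upper == pd$lower
  free <- which(!fixed)
  x_fixed <- pd$lower
  g0 <- as.numeric(pd$A[, fixed, drop = FALSE] %*% pd$lower[fixed])
  e0 <- sum(pd$e[fixed] * pd$lower[fixed])

  if (length(free) == 0) {
    x <- stats::setNames(pd$lower, pd$ids)
    tot <- diet_totals(x, table)
    d <- if (tot$defined) macro_distance(tot, cfg$targets) else NA_real_
    return(.finish_solution(x, tot, d, "optimal", cfg, table, eer_kj,
                            list(note = "all servings fixed by bounds"),
                            round))
  }

  A <- pd$A[, free, drop = FALSE]
  e <- pd$e[free]
  L <- pd$lower[free]
  U <- pd$upper[free]
  obj <- .objective_fns(A, e, g0, e0, pd$targets)

  fin <- is.finite(U)
  ui <- diag(length(free))
  ci <- L
  if (any(fin)) {
    ui <- rbind(ui, -diag(length(free))[fin, , drop = FALSE])
    ci <- c(ci, -U[fin])
  }
  ui <- rbind(ui, -e)
  ci <- c(ci, -(eer_kj - e0))   # cap net of energy fixed by bounds

  slack <- eer_kj - min_energy
  make_start <- function(w, frac) {
    d <- w / max(w)
    denom <- sum(e * d)
    s <- if (denom > 0) frac * slack / denom else 1
    x <- L + pmin(s * d, ifelse(fin, 0.95 * (U - L), s * d))
    # keep strictly interior on every face
    x <- pmax(x, L + ifelse(fin, 1e-9 * pmax(U - L, 1e-6), 1e-9))
    if (sum(e * x) + e0 <= 0) x <- x + 1e-6
    x
  }
  starts <- list(make_start(rep(1, length(free)), 0.5),
                 make_start(rep(1, length(free)), 0.9),
                 make_start(rep(1, length(free)), 0.1))
  for (i in seq_len(n_starts)) {
    starts[[length(starts) + 1]] <-
      make_start(stats::runif(length(free), 0.05, 1),
                 stats::runif(1, 0.05, 0.95))
  }

  run_from <- function(x0) {
    tryCatch(
      stats::constrOptim(x0, f = obj$f, grad = obj$grad, ui = ui, ci = ci,
                         method = "BFGS", outer.eps = 1e-10,
                         control = list(maxit = 200, reltol = 1e-14)),
      error = function(err) NULL)
  }

  best <- NULL
  n_run <- 0
  for (x0 in starts) {
    res <- run_from(x0)
    n_run <- n_run + 1
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
    if (best$value < (tol)^2 * 1e-4) break
  }
  if (is.null(best)) {
    x <- stats::setNames(pd$lower, pd$ids)
    tot <- diet_totals(x, table)
    d <- if (tot$defined) macro_distance(tot, cfg$targets) else NA_real_
    return(.finish_solution(x, tot, d, "not_converged", cfg, table,
                            eer_kj, list(starts_run = n_run), round))
  }

  # tie-break: scale out along the ray (distance is scale-invariant),
  # then re-polish from the scaled point and re-scale once more
  scale_out <- function(xf) {
    x_full <- x_fixed
    x_full[free] <- xf
    cs <- .ray_scale(x_full, pd$e, pd$upper, eer_kj)
    # scaling the full vector would also move fixed nonzero servings
    if (any(fixed & x_fixed > 0)) cs <- 1
    xf * cs
  }
  xf <- scale_out(best$par)
  res2 <- run_from(pmax(xf * (1 - 1e-9), L + 1e-12))
  if (!is.null(res2) && res2$value < best$value - 1e-15) {
    best <- res2
    xf <- scale_out(res2$par)
  }
  # when a serving maximum truncates the ray short of the cap, grow the
  # unblocked groups directly under the distance constraint
  if (sum(e * xf) + e0 < eer_kj * (1 - 1e-9)) {
    xf <- .maximize_energy(obj, e, eer_kj - e0, xf, L, U, best$value,
                           ui, ci, d_tol = tol)
    xf <- scale_out(xf)
  }

  x_full <- x_fixed
  x_full[free] <- pmin(pmax(xf, L), U)
  x <- stats::setNames(x_full, pd$ids)
  tot <- diet_totals(x, table)
  d <- macro_distance(tot, cfg$targets)
  status <- if (best$convergence == 0 || d <= sqrt(best$value) + tol) {
    "optimal"
  } else {
    "not_converged"
  }
  .finish_solution(x, tot, d, status, cfg, table, eer_kj,
                   list(starts_run = n_run, seed = seed,
                        objective_sq = best$value), round)
}

.finish_solution <- function(x, tot, d, status, cfg, table, eer_kj,
                             diagnostics, round) {
  rounded <- NULL
  tot_r <- NULL
  if (round && status %in% c("optimal", "not_converged")) {
    rp <- round_prescription(x, cfg, table, eer_kj)
    rounded <- rp
    tot_r <- diet_totals(rp$servings, table)
  }
  structure(list(prescription = x, rounded = rounded, totals = tot,
                 totals_rounded = tot_r, distance = d, status = status,
                 eer_kj = eer_kj, diagnostics = diagnostics),
            class = "serving_solution")
}

#' @export
print.serving_solution <- function(x, ...) {
  cat("Serving prescription (status:", x$status, ")\n")
  if (x$status == "infeasible") {
    cat(sprintf("  minima exceed the energy cap by %.1f kJ\n",
                x$infeasible_margin_kj))
    return(invisible(x))
  }
  print(round(x$prescription, 3))
  cat(sprintf("  distance from targets: %.4f percentage points\n",
              x$distance))
  cat(sprintf("  energy: %.1f kJ of %.1f kJ allowed\n",
              x$totals$total_energy_kj, x$eer_kj))
  if (!is.null(x$rounded)) {
    cat("  rounded to serving grid:\n")
    print(round(x$rounded$servings, 3))
  }
  invisible(x)
}

#' Exhaustive grid-search oracle
#'
#' Enumerates every serving combination on a regular grid (anchored at
#' each group's minimum) and returns the feasible point of minimal
#' distance, breaking ties by maximal energy. Intended as an independent
#' check of [solve_servings()] on small instances; refuses more than
#' `max_points` grid points.
#'
#' @inheritParams solve_servings
#' @param grid servings increment of the enumeration grid.
#' @param max_points refusal threshold on the grid size.
#' @return object of class `serving_solution` (no rounding pass).
#' @export
brute_force_solve <- function(cfg, table, eer_kj, grid = 0.5,
                              max_points = 1e7) {
  pd <- .problem_data(cfg, table)
  if (pd$n > 5) {
    stop("brute force limited to 5 groups (got ", pd$n, ")", call. = FALSE)
  }
  axes <- lapply(seq_len(pd$n), function(i) {
    hi <- pd$upper[i]
    if (!is.finite(hi)) {
      # first grid point whose solo energy exceeds the cap
      hi <- if (pd$e[i] > 0) {
        max(pd$lower[i],
            pd$lower[i] +
              grid * ceiling((eer_kj / pd$e[i] - pd$lower[i]) / grid))
      } else {
        pd$lower[i]
      }
    }
    seq(pd$lower[i], hi + 1e-9, by = grid)
  })
  npts <- prod(vapply(axes, length, 1L))
  if (npts > max_points) {
    stop("grid has ", format(npts, big.mark = ","), " points (limit ",
         format(max_points, big.mark = ","),
         "); coarsen the grid or bound the servings", call. = FALSE)
  }
  X <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(X) <- pd$ids
  G <- X %*% t(pd$A)                      # grams per macro
  energy <- as.numeric(G %*% KJ_PER_G)
  feasible <- energy <= eer_kj * (1 + 1e-12) & energy > 0
  if (!any(feasible)) {
    min_energy <- sum(pd$e * pd$lower)
    status <- if (min_energy > eer_kj) "infeasible" else "infeasible"
    return(structure(list(
      prescription = stats::setNames(pd$lower, pd$ids),
      rounded = NULL, totals = NULL, totals_rounded = NULL,
      distance = NA_real_, status = status,
      infeasible_margin_kj = max(0, min_energy - eer_kj),
      eer_kj = eer_kj,
      diagnostics = list(grid = grid, points = npts)),
      class = "serving_solution"))
  }
  P <- 100 * sweep(G[feasible, , drop = FALSE], 2, KJ_PER_G, `*`) /
    energy[feasible]
  dev <- sweep(P, 2, pd$targets, `-`)
  d <- sqrt(rowSums(dev^2))
  dmin <- min(d)
  tied <- which(d <= dmin + 1e-9)
  pick <- tied[which.max(energy[feasible][tied])]
  x <- stats::setNames(X[which(feasible)[pick], ], pd$ids)
  tot <- diet_totals(x, table)
  structure(list(prescription = x, rounded = NULL, totals = tot,
                 totals_rounded = NULL,
                 distance = macro_distance(tot, cfg$targets),
                 status = "optimal", eer_kj = eer_kj,
                 diagnostics = list(grid = grid, points = npts)),
            class = "serving_solution")
}

#' Round a prescription onto the serving grid
#'
#' Snaps each group's servings to its increment (default half servings;
#' whole servings for constraints flagged `integral`), then repairs the
#' result: servings are pushed back above their minima, strict maxima are
#' respected, and if rounding pushed total energy over the cap the groups
#' that were rounded up are rounded down instead, largest energy excess
#' first. Groups with a `weekly_unit_g` in the food table (fish, eggs,
#' cheese: prescribed in fractional daily servings standing for weekly
#' portions) are exempt from snapping.
#'
#' @param servings named numeric prescription (feasible).
#' @param cfg a [study_config()].
#' @param table a [food_table()].
#' @param eer_kj energy cap, kJ/day.
#' @return list: `servings` (rounded prescription), `energy_change_kj`
#'   (rounded minus continuous), `feasible` (logical), `note`.
#' @export
round_prescription <- function(servings, cfg, table, eer_kj) {
  pd <- .problem_data(cfg, table)
  x <- servings[pd$ids]
  names(x) <- pd$ids
  inc <- pd$increment
  inc[pd$integral] <- pmax(inc[pd$integral], 1)
  exempt <- if ("weekly_unit_g" %in% names(table)) {
    !is.na(table$weekly_unit_g)
  } else {
    rep(FALSE, pd$n)
  }
  snap <- ifelse(exempt, x, round(x / inc) * inc)
  names(snap) <- pd$ids
  # restore minima and maxima on the grid
  low_viol <- snap < pd$lower - 1e-9
  snap[low_viol] <- (ceiling(pd$lower / inc - 1e-9) * inc)[low_viol]
  hi <- pd$upper
  hi_viol <- is.finite(hi) & snap > hi + 1e-9
  snap[hi_viol] <- (floor(hi / inc + 1e-9) * inc)[hi_viol]
  if (any(snap < pd$lower - 1e-9)) {
    return(list(servings = x, energy_change_kj = 0, feasible = FALSE,
                note = "no feasible rounding (bound conflict); continuous values retained"))
  }
  energy0 <- sum(pd$e * x)
  energy <- sum(pd$e * snap)
  if (energy > eer_kj * (1 + 1e-9)) {
    # undo round-ups, biggest energy excess first, while minima allow
    up <- which(snap > x + 1e-12 & !exempt)
    up <- up[order(pd$e[up] * (snap[up] - x[up]), decreasing = TRUE)]
    for (i in up) {
      cand <- snap[i] - inc[i]
      if (cand >= pd$lower[i] - 1e-9) {
        snap[i] <- cand
        energy <- sum(pd$e * snap)
        if (energy <= eer_kj * (1 + 1e-9)) break
      }
    }
  }
  if (energy > eer_kj * (1 + 1e-9)) {
    return(list(servings = x, energy_change_kj = 0, feasible = FALSE,
                note = "no feasible rounding within the energy cap; continuous values retained"))
  }
  list(servings = snap, energy_change_kj = energy - energy0,
       feasible = TRUE, note = "")
}
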