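## Fixed points, stability, nullclines, one- and two-parameter continuation,
## and linear-approximation pathway strengths for the rate model.

# signed weight matrix: presynaptic P excites, B and A inhibit; the B->A
# entry is scaled by the efficacy e and the A<-P entry by (1 + z)
.signed_W <- function(params, e, z = 0) {
  S <- params$W * matrix(c(1, -1, -1), 3, 3, byrow = TRUE)
  S["A", "B"] <- S["A", "B"] * e
  S["A", "P"] <- S["A", "P"] * (1 + z)
  S
}

# steady-state residual g(r) = -r + f(S r + t) and its Jacobian
.ss_fun <- function(params, e, z = 0) {
  S <- .signed_W(params, e, z)
  k <- params$k; t <- params$t; F <- params$F
  list(
    g = function(r) {
      -r + softplusActivation(as.numeric(S %*% r), k, t, F)
    },
    J = function(r) {
      a <- k * (as.numeric(S %*% r) + t)
      sig <- stats::plogis(a)
      -diag(3) + (F * k * sig) * S
    })
  }

.newton <- function(fun, r0, tol = 1e-10, maxit = 100) {
  r <- r0
  g <- fun$g(r)
  for (it in seq_len(maxit)) {
    if (max(abs(g)) < tol) return(list(root = r, residual = max(abs(g))))
    J <- fun$J(r)
    step <- tryCatch(solve(J, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      r_new <- r + lambda * step
      g_new <- fun$g(r_new)
      if (all(is.finite(g_new)) &&
          (max(abs(g_new)) < max(abs(g)) || lambda < 1e-6)) break
      lambda <- lambda / 2
    }
    r <- r_new; g <- g_new
  }
  if (max(abs(g)) < tol) list(root = r, residual = max(abs(g))) else NULL
}

.default_seeds <- function() {
  list(c(0, 0, 0), c(0, 0, 12.5), c(44, 92, 0), c(2, 1, 12), c(20, 45, 5),
       c(0, 0, 25), c(10, 20, 2), c(80, 160, 0), c(150, 300, 0),
       c(400, 700, 0), c(44, 92, 12), c(5, 5, 5))
}

#' Fixed points of the rate model
#'
#' All roots of the three-dimensional steady-state system, found by damped
#' Newton iteration with an analytic Jacobian from a set of multi-start seeds
#' (known approximate states plus a coarse lattice; additional seeds may be
#' supplied).  Duplicates are merged, and stability is classified from the
#' eigenvalues of the Jacobian of the rate ODEs with the efficacy `e` (and
#' facilitation `z`) treated as parameters.
#'
#' @param params a `rate_params`.
#' @param e efficacy of the B->A connection, in `[0, 1]` (values above 1 are
#'   admitted for weight sweeps expressed through `e`).
#' @param z facilitation level scaling the A<-P weight by `(1 + z)`.
#' @param extra_seeds optional list of additional 3-vectors.
#' @param tol residual tolerance.
#' @return an object of class `fixed_points`: data.frame with columns `P`,
#'   `B`, `A`, `stable`, `residual`; eigenvalues in `attr(, "eigenvalues")`.
#' @export
steadyStates <- function(params, e, z = 0, extra_seeds = list(), tol = 1e-10) {
  stopifnot(e >= 0)
  fun <- .ss_fun(params, e, z)
  seeds <- c(.default_seeds(), extra_seeds)
  roots <- list()
  for (s in seeds) {
    res <- .newton(fun, as.numeric(s), tol = tol)
    if (is.null(res)) next
    r <- pmax(res$root, 0)  # softplus fixed points are positive; clean -0
    dup <- any(vapply(roots, function(q)
      max(abs(q - r)) < 1e-5 * (1 + max(abs(r))), TRUE))
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  if (!length(roots))
    stop("root finder exhausted all seeds without convergence")
  ord <- order(vapply(roots, function(r) r[1] + r[2], 0))
  roots <- roots[ord]
  eig <- lapply(roots, function(r)
    eigen(diag(1 / params$tau) %*% fun$J(r), only.values = TRUE)$values)
  out <- data.frame(
    P = vapply(roots, `[`, 0, 1), B = vapply(roots, `[`, 0, 2),
    A = vapply(roots, `[`, 0, 3),
    stable = vapply(eig, function(ev) all(Re(ev) < 0), TRUE),
    residual = vapply(roots, function(r) max(abs(fun$g(r))), 0))
  structure(out, class = c("fixed_points", "data.frame"), eigenvalues = eig,
            e = e, z = z)
}

#' Nullclines of the rate model
#'
#' For the `"PB"` plane, the right-hand sides of the P and B equations are
#' evaluated on a grid with A replaced by its steady-state response to
#' (P, B); the zero contours of the returned matrices are the nullclines.
#' The `"AP"` plane does the same with B at steady state.  The `"Be"` plane
#' returns the slow e-nullcline `e*(B) = 1 / (1 + eta_d tau_d B)`; the slow
#' facilitation nullcline `z*(P) = eta_f P z_max tau_f / (1 + eta_f P tau_f)`
#' is always included for reference.
#'
#' @param params a `rate_params`.
#' @param plane `"PB"`, `"AP"` or `"Be"`.
#' @param e efficacy treated as a parameter.
#' @param grid evaluation grid for the two free rates (spikes/s), or for B in
#'   the `"Be"` plane.
#' @return a list with the grid, the two RHS matrices (for rate planes), and
#'   closed-form `e_nullcline` / `z_nullcline` functions.
#' @export
nullclines <- function(params, plane = c("PB", "AP", "Be"), e = 0.5,
                       grid = seq(0, 100, length.out = 201)) {
  plane <- match.arg(plane)
  e_null <- function(B) 1 / (1 + params$eta_d * params$tau_d * B)
  z_null <- function(P) params$eta_f * P * params$z_max * params$tau_f /
    (1 + params$eta_f * P * params$tau_f)
  if (plane == "Be")
    return(list(grid = grid, e_nullcline = e_null, z_nullcline = z_null,
                e_on_grid = e_null(grid)))
  S <- .signed_W(params, e)
  k <- params$k; tt <- params$t; F <- params$F
  solved_third <- function(fixed_idx, free1, free2, solve_idx) {
    # steady-state response of population solve_idx given the other two
    inp <- S[solve_idx, fixed_idx[1]] * free1 + S[solve_idx, fixed_idx[2]] * free2
    h <- function(x) softplusActivation(
      inp + S[solve_idx, solve_idx] * x, k[solve_idx], tt[solve_idx], F) - x
    upper <- 2000
    if (h(0) <= 0) return(0)
    uniroot(h, c(0, upper), tol = 1e-10)$root
  }
  if (plane == "PB") { i1 <- 1; i2 <- 2; i3 <- 3 } else { i1 <- 3; i2 <- 1; i3 <- 2 }
  n <- length(grid)
  rhs1 <- rhs2 <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    r <- numeric(3)
    r[i1] <- grid[a]; r[i2] <- grid[b]
    r[i3] <- solved_third(c(i1, i2), grid[a], grid[b], i3)
    f <- softplusActivation(as.numeric(S %*% r), k, tt, F) - r
    rhs1[a, b] <- f[i1]; rhs2[a, b] <- f[i2]
  }
  list(grid = grid, axes = POPS[c(i1, i2)], rhs1 = rhs1, rhs2 = rhs2,
       e_nullcline = e_null, z_nullcline = z_null)
}

# parameter accessors for continuation sweeps
.param_setter <- function(name) {
  if (name == "e") return(function(params, v) list(params = params, e = v, z = 0))
  if (name == "z") return(function(params, v) list(params = params, e = NA, z = v))
  if (grepl("^W_[PBA][PBA]$", name)) {
    post <- substr(name, 3, 3); pre <- substr(name, 4, 4)
    return(function(params, v) {
      params$W[post, pre] <- v
      list(params = params, e = NA, z = 0)
    })
  }
  stop("unknown parameter: ", name)
}

#' One-parameter bifurcation diagram
#'
#' Sweeps one parameter (the efficacy `e`, any weight `W_IJ`, or the
#' facilitation level `z`) over a range, tracking all fixed points by
#' multi-start Newton with the previous solutions carried along as seeds
#' (natural-parameter continuation).  Parameter values where the number of
#' fixed points changes are refined by bisection to `refine_tol` and reported
#' as folds.  Branch points whose rates exceed `cap` are truncated and
#' reported as blow-up (the recurrent-excitation sweep has no fold: the
#' active branch grows without bound, and rates above the refractory ceiling
#' of the underlying spiking neurons are meaningless).
#'
#' @param params a `rate_params`.
#' @param name swept parameter (`"e"`, `"z"`, or `"W_PP"` ... `"W_AA"` with
#'   post-pre subscripts).
#' @param range length-2 numeric range.
#' @param e efficacy used while sweeping a weight or `z`.
#' @param n_grid sweep resolution.
#' @param cap blow-up cap on rates (spikes/s), defaults to 1000 = 1/t_refr.
#' @param refine_tol bisection tolerance on fold/blow-up locations.
#' @return an object of class `bifurcation_diagram`: `points` (data.frame of
#'   parameter value, rates, stability), `folds` (refined fold locations),
#'   `blowup` (truncation location or NA), `name`, `cap`.
#' @export
continueParameter <- function(params, name, range, e = 0.5, n_grid = 201,
                              cap = 1000, refine_tol = 1e-3) {
  stopifnot(length(range) == 2, all(is.finite(range)))
  setter <- .param_setter(name)
  grid <- seq(range[1], range[2], length.out = n_grid)

  fps_at <- function(v, carry = list()) {
    s <- setter(params, v)
    ee <- if (is.na(s$e)) e else s$e
    fp <- tryCatch(
      steadyStates(s$params, ee, s$z, extra_seeds = carry),
      error = function(err) NULL)
    if (is.null(fp)) return(data.frame(P = numeric(0), B = numeric(0),
                                       A = numeric(0), stable = logical(0),
                                       residual = numeric(0)))
    fp
  }
  carry <- list()
  pts <- vector("list", n_grid)
  n_all <- n_cap <- integer(n_grid)
  for (i in seq_along(grid)) {
    fp <- fps_at(grid[i], carry)
    carry <- lapply(seq_len(nrow(fp)), function(r) as.numeric(fp[r, 1:3]))
    n_all[i] <- nrow(fp)
    within_cap <- fp$P <= cap & fp$B <= cap & fp$A <= cap
    n_cap[i] <- sum(within_cap)
    if (nrow(fp))
      pts[[i]] <- cbind(param = grid[i], fp[within_cap, , drop = FALSE])
  }
  points <- do.call(rbind, pts)

  refine <- function(lo, hi, count_fn, lo_val) {
    carry2 <- carry
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      fp <- fps_at(mid, carry2)
      carry2 <- lapply(seq_len(nrow(fp)), function(r) as.numeric(fp[r, 1:3]))
      if (count_fn(fp) == lo_val) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  count_all_fn <- function(fp) nrow(fp)
  count_cap_fn <- function(fp)
    sum(fp$P <= cap & fp$B <= cap & fp$A <= cap)

  folds <- numeric(0)
  blowup <- NA_real_
  for (i in seq_len(n_grid - 1)) {
    if (n_all[i + 1] != n_all[i]) {
      folds <- c(folds, refine(grid[i], grid[i + 1], count_all_fn, n_all[i]))
    } else if (n_cap[i + 1] != n_cap[i]) {
      blowup <- refine(grid[i], grid[i + 1], count_cap_fn, n_cap[i])
    }
  }
  structure(list(points = points, folds = folds, blowup = blowup,
                 name = name, range = range, cap = cap, e = e),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("<bifurcation_diagram> %s in [%g, %g]: %d branch points\n",
              x$name, x$range[1], x$range[2], nrow(x$points)))
  if (length(x$folds))
    cat("  folds at:", paste(sprintf("%.4f", x$folds), collapse = ", "), "\n")
  if (!is.na(x$blowup))
    cat(sprintf("  branch truncated (rates > %g /s) beyond %.4f\n",
                x$cap, x$blowup))
  invisible(x)
}

#' Two-parameter bistable region
#'
#' Classifies each point of a dense grid over a pair of parameters by its
#' fixed-point count (three fixed points, two of them stable, marks
#' bistability) and returns the bistable mask together with the boundary
#' polyline.
#'
#' @param params a `rate_params`.
#' @param pair character 2-vector of parameter names (as in
#'   [continueParameter()], plus `"k_P"`/`"t_P"` etc. for activation
#'   parameters).
#' @param ranges list of two length-2 ranges.
#' @param resolution grid resolution per axis.
#' @param e efficacy used when neither parameter is `e`.
#' @param cap rate cap (spikes/s).
#' @return list with `x`, `y`, `bistable` (logical matrix), `n_fp` (count
#'   matrix) and `boundary` (list of contour polylines).
#' @export
bistableRegion2d <- function(params, pair, ranges, resolution = 41, e = 0.5,
                             cap = 1000) {
  set_one <- function(params_e, name, v) {
    params <- params_e$params; ee <- params_e$e
    if (name == "e") ee <- v
    else if (grepl("^W_", name)) {
      params$W[substr(name, 3, 3), substr(name, 4, 4)] <- v
    } else if (grepl("^k_", name)) {
      params$k[substr(name, 3, 3)] <- v
    } else if (grepl("^t_", name)) {
      params$t[substr(name, 3, 3)] <- v
    } else stop("unknown parameter: ", name)
    list(params = params, e = ee)
  }
  xs <- seq(ranges[[1]][1], ranges[[1]][2], length.out = resolution)
  ys <- seq(ranges[[2]][1], ranges[[2]][2], length.out = resolution)
  n_fp <- matrix(0L, resolution, resolution)
  for (i in seq_along(xs)) for (j in seq_along(ys)) {
    pe <- set_one(list(params = params, e = e), pair[1], xs[i])
    pe <- set_one(pe, pair[2], ys[j])
    fp <- tryCatch(steadyStates(pe$params, pe$e), error = function(err) NULL)
    if (is.null(fp)) next
    ok <- fp$P <= cap & fp$B <= cap & fp$A <= cap
    n_fp[i, j] <- sum(ok)
  }
  bistable <- n_fp >= 3
  boundary <- grDevices::contourLines(xs, ys, n_fp, levels = 2)
  list(x = xs, y = ys, bistable = bistable, n_fp = n_fp, boundary = boundary,
       pair = pair)
}

#' Pathway strengths and the four circuit requirements
#'
#' Linear-approximation pathway strengths: with `f_I(x) ~ F k_I (x + t_I)`,
#' the strength of the direct pathway J -> I is
#' `k_I w_IJ / (1 - k_I w_II)` where `w` carries the synaptic sign (P
#' excites; B, A inhibit), and an indirect pathway is the product of its two
#' constituents.  The four requirements of the disinhibitory motif are
#' evaluated with their margins:
#'
#' 1. P->B->A stronger than P->A (activating P suppresses A):
#'    `W_AP (1 + k_B W_BB) < k_B W_BP W_AB`.
#' 2. P->B stronger than P->A->B (activating P recruits B):
#'    `W_BP (1 + k_A W_AA) > k_A W_AP W_BA`.
#' 3. B->A->P stronger than B->P (activating B disinhibits P):
#'    `W_PB (1 + k_A W_AA) < k_A W_AB W_PA`.
#' 4. A->P stronger than A->B->P (silencing A releases P):
#'    `W_PA (1 + k_B W_BB) > k_B W_BA W_PB`.
#'
#' @param params a `rate_params`.
#' @return an object of class `pathway_report`: data.frames `direct` and
#'   `indirect` (signed strengths) and `requirements` (lhs, rhs, satisfied,
#'   margin > 0 iff satisfied).
#' @export
pathwayStrengths <- function(params) {
  W <- params$W; k <- params$k
  den <- c(P = 1 - k[["P"]] * W["P", "P"],
           B = 1 + k[["B"]] * W["B", "B"],
           A = 1 + k[["A"]] * W["A", "A"])
  if (den[["P"]] <= 0)
    warning("k_P W_PP >= 1: the linear approximation diverges for pathways into P")
  sgn <- c(P = 1, B = -1, A = -1)
  S <- function(pre, post) sgn[[pre]] * k[[post]] * W[post, pre] / den[[post]]
  direct <- data.frame(
    pathway = c("P->A", "P->B", "B->A", "B->P", "A->P", "A->B"),
    strength = c(S("P", "A"), S("P", "B"), S("B", "A"), S("B", "P"),
                 S("A", "P"), S("A", "B")))
  ind <- function(a, b, c) S(a, b) * S(b, c)
  indirect <- data.frame(
    pathway = c("P->B->A", "P->A->B", "B->A->P", "A->B->P"),
    strength = c(ind("P", "B", "A"), ind("P", "A", "B"), ind("B", "A", "P"),
                 ind("A", "B", "P")))
  req <- data.frame(
    requirement = c("P->B->A > P->A", "P->B > P->A->B", "B->A->P > B->P",
                    "A->P > A->B->P"),
    lhs = c(W["A", "P"] * (1 + k[["B"]] * W["B", "B"]),
            k[["A"]] * W["A", "P"] * W["B", "A"],
            W["P", "B"] * (1 + k[["A"]] * W["A", "A"]),
            k[["B"]] * W["B", "A"] * W["P", "B"]),
    rhs = c(k[["B"]] * W["B", "P"] * W["A", "B"],
            W["B", "P"] * (1 + k[["A"]] * W["A", "A"]),
            k[["A"]] * W["A", "B"] * W["P", "A"],
            W["P", "A"] * (1 + k[["B"]] * W["B", "B"])))
  req$satisfied <- req$rhs > req$lhs
  req$margin <- req$rhs - req$lhs
  structure(list(direct = direct, indirect = indirect, requirements = req),
            class = "pathway_report")
}

#' @export
print.pathway_report <- function(x, ...) {
  cat("<pathway_report>\n")
  print(cbind(x$requirements[, c("requirement", "satisfied")],
              margin = round(x$requirements$margin, 3)))
  invisible(x)
}
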