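# Linear programming layer. The steady-state problem is
#   optimize c'v  subject to  S v = 0,  lb <= v <= ub.
# It is solved by a dense bounded-variable two-phase primal simplex with
# Bland's rule (anti-cycling), written for the small, often degenerate LPs
# that enzyme-constrained toy models produce: all right-hand sides are zero
# and coefficient magnitudes span from 1/kcat_h (~1e-5) to default flux
# bounds (1e3). Variables are shifted to x = v - lb >= 0, bound ranges are
# scaled to 1 and balance rows equilibrated before solving.

LP_BIG <- 1e6

# Bounded-variable two-phase simplex:
#   maximize c'x  s.t.  A x = b,  0 <= x <= u   (u finite).
# Returns list(status, x). Bland's rule (smallest eligible index) guarantees
# termination; basis systems are re-factorized every iteration, which is
# cheap at these sizes and avoids drift.
simplex_bounded <- function(A, b, c_obj, u, maximize = TRUE, tol = 1e-9,
                            max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  if (!maximize) c_obj <- -c_obj
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  Aa <- cbind(A, diag(m))
  n_tot <- n + m
  ua <- c(u, b + 1)
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, n_tot)

  run_phase <- function(cost, basis, at_upper) {
    for (it in seq_len(max_iter)) {
      B <- Aa[, basis, drop = FALSE]
      nb <- setdiff(seq_len(n_tot), basis)
      xn <- ifelse(at_upper[nb], ua[nb], 0)
      xB <- tryCatch(
        as.numeric(solve(B, b - Aa[, nb, drop = FALSE] %*% xn)),
        error = function(e) NULL)
      if (is.null(xB)) return(list(status = "numerical", basis = basis,
                                   at_upper = at_upper))
      y <- as.numeric(solve(t(B), cost[basis]))
      d <- cost[nb] - as.numeric(crossprod(Aa[, nb, drop = FALSE], y))
      eligible <- (!at_upper[nb] & d > tol) | (at_upper[nb] & d < -tol)
      if (!any(eligible)) {
        return(list(status = "optimal", basis = basis, at_upper = at_upper,
                    xB = xB, nb = nb, xn = xn))
      }
      j <- nb[which(eligible)[1]]  # Bland: nb is in ascending order
      dir <- if (at_upper[j]) -1 else 1
      w <- as.numeric(solve(B, Aa[, j])) * dir  # xB moves by -w * t
      t_best <- ua[j]
      leave <- NA_integer_
      leave_upper <- FALSE
      for (k in seq_len(m)) {
        if (w[k] > tol) {
          tt <- xB[k] / w[k]
        } else if (w[k] < -tol) {
          tt <- (ua[basis[k]] - xB[k]) / (-w[k])
        } else next
        if (tt < t_best - 1e-12 ||
            (tt < t_best + 1e-12 && !is.na(leave) &&
             basis[k] < basis[leave])) {
          t_best <- tt
          leave <- k
          leave_upper <- w[k] < 0
        }
      }
      if (is.na(leave)) {
        at_upper[j] <- !at_upper[j]  # bound flip, basis unchanged
      } else {
        lv <- basis[leave]
        basis[leave] <- j
        at_upper[lv] <- leave_upper
        at_upper[j] <- FALSE
      }
    }
    list(status = "iteration_limit", basis = basis, at_upper = at_upper)
  }

  # phase 1: drive the artificials to zero
  ph1 <- run_phase(c(rep(0, n), rep(-1, m)), basis, at_upper)
  if (ph1$status != "optimal") return(list(status = ph1$status, x = NULL))
  art_val <- sum(full_solution(ph1, n_tot, ua)[n + seq_len(m)])
  if (art_val > 1e-7) return(list(status = "infeasible", x = NULL))
  ua[n + seq_len(m)] <- 0  # lock artificials for phase 2
  ph2 <- run_phase(c(c_obj, rep(0, m)), ph1$basis, ph1$at_upper)
  if (ph2$status != "optimal") return(list(status = ph2$status, x = NULL))
  x <- full_solution(ph2, n_tot, ua)
  list(status = "optimal", x = x[seq_len(n)])
}

full_solution <- function(phase, n_tot, ua) {
  x <- numeric(n_tot)
  x[phase$nb] <- ifelse(phase$at_upper[phase$nb], ua[phase$nb], 0)
  x[phase$basis] <- phase$xB
  x
}

#' Solve a flux LP on a model
#'
#' @param model a `metabolic_model` or `ec_model`.
#' @param objective named numeric vector of objective coefficients over
#'   reaction ids; `NULL` uses the model's objective reaction.
#' @param direction `"max"` or `"min"`; `NULL` uses the model's objective
#'   direction.
#' @param big cap substituted for infinite bounds that cannot be tightened
#'   by implied-bound propagation.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `value`, and the flux vector `fluxes`.
#' @export
solve_lp <- function(model, objective = NULL, direction = NULL,
                     big = LP_BIG) {
  rxns <- model$reactions
  n <- nrow(rxns)
  if (is.null(objective)) {
    if (is.null(model$objective)) {
      stop("no objective given and the model has none", call. = FALSE)
    }
    objective <- stats::setNames(1, model$objective$reaction)
  }
  if (is.null(direction)) {
    direction <- if (!is.null(model$objective)) model$objective$direction
                 else "max"
  }
  a <- numeric(n)
  names(a) <- rxns$id
  a[names(objective)] <- objective
  lb <- pmax(rxns$lb, -big)
  ub <- pmin(rxns$ub, big)
  capped <- rxns$ub > big
  S0 <- stoich_matrix(model)
  # Tighten infinite upper bounds by one pass of implied-bound propagation
  # through the balance rows (e.g. an enzyme usage is implied by the
  # capacity of the columns consuming its enzyme row, or by the pool), so
  # magnitudes stay commensurate.
  for (j in which(!is.finite(rxns$ub))) {
    best <- big
    for (i in which(S0[, j] != 0)) {
      coefs <- S0[i, ]
      others <- setdiff(which(coefs != 0), j)
      ratio <- -coefs[others] / coefs[j]
      contrib <- ifelse(ratio > 0, ratio * rxns$ub[others],
                        ratio * rxns$lb[others])
      if (all(is.finite(contrib))) best <- min(best, sum(contrib))
    }
    ub[j] <- min(ub[j], max(best * (1 + 1e-9), lb[j]))
    capped[j] <- best >= big
  }
  S <- S0[rowSums(S0 != 0) > 0, , drop = FALSE]
  # substitute out variables pinned by equal bounds
  fixed <- (ub - lb) <= 1e-15
  free <- which(!fixed)
  rhs <- as.numeric(-S %*% ifelse(fixed, lb, 0)) -
    as.numeric(S[, free, drop = FALSE] %*% lb[free])
  Sf <- S[, free, drop = FALSE]
  keep <- rowSums(Sf != 0) > 0
  if (any(!keep & abs(rhs) > 1e-9)) {
    return(list(status = "infeasible", value = NA_real_,
                fluxes = stats::setNames(rep(NA_real_, n), rxns$id)))
  }
  Sf <- Sf[keep, , drop = FALSE]
  b3 <- rhs[keep]
  nf <- length(free)
  v <- stats::setNames(lb, rxns$id)  # fixed variables sit at their bound
  if (nf == 0L) {
    return(list(status = "optimal", value = sum(a * v), fluxes = v))
  }
  # equilibrate: scale each variable by its bound range and each balance
  # row by its largest coefficient
  s_col <- (ub - lb)[free]
  A <- sweep(Sf, 2, s_col, "*")
  if (nrow(A)) {
    r_row <- 1 / apply(abs(A), 1, max)
    A <- A * r_row
    b3 <- b3 * r_row
  }
  res <- simplex_bounded(A, b3, a[free] * s_col, rep(1, nf),
                         maximize = direction == "max")
  status <- res$status
  value <- NA_real_
  if (status == "optimal") {
    v[free] <- res$x * s_col + lb[free]
    value <- sum(a * v)
    if (any(capped & v > 0.99 * big) || abs(value) > 0.1 * big) {
      status <- "unbounded"
    }
  } else {
    v[] <- NA_real_
  }
  list(status = status, value = value, fluxes = v)
}

# Bundle an LP solution into a simulation result carrying enzyme usages and
# pool mass.
sim_result <- function(model, lp, provenance) {
  usages <- pool_usage <- NULL
  if (inherits(model, "ec_model") && lp$status == "optimal") {
    draw_ids <- grep("^draw_prot_", names(lp$fluxes), value = TRUE)
    usages <- stats::setNames(lp$fluxes[draw_ids],
                              sub("^draw_prot_", "", draw_ids))
    mw <- stats::setNames(model$enzymes$mw_kda, model$enzymes$protein_id)
    pool_usage <- sum(mw[names(usages)] * usages)
  }
  structure(list(status = lp$status, objective = lp$value,
                 fluxes = lp$fluxes, usages = usages,
                 pool_usage = pool_usage, provenance = provenance),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> status: %s; objective: %s\n", x$status,
              format(x$objective, digits = 6)))
  if (!is.null(x$pool_usage)) {
    cat(sprintf("total enzyme mass: %.6g g/gDW\n", x$pool_usage))
  }
  cat("recipe:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

# Mass-weighted (or plain) enzyme usage objective over the usage columns.
enzyme_mass_objective <- function(ec, mass_weighted = TRUE) {
  draw_ids <- grep("^draw_prot_", ec$reactions$id, value = TRUE)
  prot <- sub("^draw_prot_", "", draw_ids)
  w <- if (mass_weighted) {
    stats::setNames(ec$enzymes$mw_kda, ec$enzymes$protein_id)[prot]
  } else rep(1, length(prot))
  stats::setNames(as.numeric(w), draw_ids)
}

# Objective vector expressing the net flux of an original reaction in an
# expanded model: forward minus backward, arm reactions standing in for
# their isozyme copies.
net_objective <- function(model, orig_id) {
  map <- model$rxn_map
  if (is.null(map)) {
    return(stats::setNames(1, orig_id))
  }
  rows <- map[map$orig_id == orig_id &
                map$role %in% c("metabolic", "arm", "usage", "pool"), ,
              drop = FALSE]
  if (!nrow(rows)) stop("unknown reaction id: ", orig_id, call. = FALSE)
  stats::setNames(as.numeric(rows$dir), rows$rxn_id)
}
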