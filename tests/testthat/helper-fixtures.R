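# Shared helpers: in-code model construction and brute-force LP oracles.

# Build a reaction table without going through the internal constructor.
rxn_df <- function(ids, lb, ub, rule = "", stoich,
                   name = "", subsystem = "") {
  n <- length(ids)
  df <- data.frame(id = ids, name = rep_len(name, n),
                   lb = rep_len(lb, n), ub = rep_len(ub, n),
                   gene_rule = rep_len(rule, n),
                   subsystem = rep_len(subsystem, n),
                   stringsAsFactors = FALSE)
  df$stoich <- stoich
  df
}

met_df <- function(ids, compartment = "c") {
  data.frame(id = ids, name = ids,
             compartment = rep_len(compartment, length(ids)),
             stringsAsFactors = FALSE)
}

# Independent oracle for the overflow fixture: enumerate the vertices of
#   { r, f >= 0, r + f <= U, cost_r * r + cost_f * f <= E }
# and maximize ATP = y_r * r + y_f * f by direct evaluation.
overflow_vertices <- function(U, E = 10, cost_r = 10, cost_f = 1,
                              y_r = 10, y_f = 2) {
  cand <- list(c(0, 0), c(U, 0), c(0, U), c(E / cost_r, 0), c(0, E / cost_f))
  det <- cost_f - cost_r  # intersection of r + f = U and cost row = E
  if (abs(det) > 0) {
    r <- (E - cost_f * U) / (cost_r - cost_f)
    cand <- c(cand, list(c(r, U - r)))
  }
  ok <- Filter(function(p) {
    p[1] >= -1e-12 && p[2] >= -1e-12 && p[1] + p[2] <= U + 1e-9 &&
      cost_r * p[1] + cost_f * p[2] <= E + 1e-9
  }, cand)
  vals <- vapply(ok, function(p) y_r * p[1] + y_f * p[2], numeric(1))
  best <- ok[[which.max(vals)]]
  list(atp = max(vals), r = best[1], f = best[2], byproduct = best[2])
}

expect_flux_equal <- function(actual, expected, tol = 1e-6) {
  expect_equal(unname(actual), expected, tolerance = tol)
}
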