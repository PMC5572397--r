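test_that("FBA on the toy model reproduces hand-derived optima", {
  ec <- make_toy_ec()
  # unconstrained usages: uptake-limited growth
  expect_equal(fba(ec)$objective, 10, tolerance = 1e-9)
  # capacity law: P2A at 5e-5 mmol/gDW and kcat 20/s caps growth at
  # 72000/h * 5e-5 = 3.6
  ec2 <- set_bounds(set_bounds(ec, "draw_prot_P2A", ub = 5e-5),
                    "draw_prot_P2B", ub = 0)
  expect_equal(fba(ec2)$objective, 3.6, tolerance = 1e-9)
  # blocking the whole catalyzed path stops growth
  ec3 <- ec
  for (p in c("P1", "P2A", "P2B")) {
    ec3 <- set_bounds(ec3, paste0("draw_prot_", p), ub = 0)
  }
  expect_equal(fba(ec3)$objective, 0, tolerance = 1e-9)
})

test_that("capacity law holds in every optimal solution", {
  ec <- set_bounds(make_toy_ec(), "draw_prot_P2A", ub = 5e-5)
  r <- fba(ec)
  for (i in seq_len(nrow(ec$kcats))) {
    k <- ec$kcats[i, ]
    v <- r$fluxes[[k$rxn_id]]
    e <- r$usages[[k$protein_id]]
    expect_lte(v, k$kcat_per_h * e / k$subunit_stoich + 1e-6)
  }
})

test_that("enzyme minimization picks the cheaper isozyme route", {
  ec <- make_toy_ec()
  r <- minimize_enzyme_usage(ec, fixed = c(GROWTH = 3.6))
  # P2A costs 50/72000 g h/mmol vs P2B 60/14400: all flux through copy 1
  expect_equal(r$fluxes[["R2No1"]], 3.6, tolerance = 1e-5)
  expect_equal(r$fluxes[["R2No2"]], 0, tolerance = 1e-9)
  # fixing nothing lets everything rest at zero
  expect_equal(minimize_enzyme_usage(ec)$objective, 0, tolerance = 1e-9)
})

test_that("identical-cost isozymes give a unique objective value", {
  mets <- met_df(c("A", "B"))
  rx <- rxn_df(c("EX", "R", "OUT"), lb = 0, ub = c(10, 1000, 1000),
               rule = c("", "G1 or G2", ""),
               stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1)))
  m <- metabolic_model(mets, rx, list(reaction = "OUT", direction = "max"))
  enz <- enzyme_table(c("P1", "P2"), c("G1", "G2"), c(10, 10),
                      c("1.1.1.1", "1.1.1.2"))
  kin <- data.frame(ec = c("1.1.1.1", "1.1.1.2"), substrate = "A",
                    organism = "o", kcat_per_s = 2)
  ec <- expand_model(m, enz, assign_kcats(m, enz, kin, "o"))
  r <- minimize_enzyme_usage(ec, fixed = c(OUT = 5))
  expect_equal(r$objective, 10 * 5 / 7200, tolerance = 1e-5)
})

test_that("chemostat protocol is respiratory below and fermentative above the switch", {
  ov <- make_overflow_model(U = 100)
  low <- chemostat(ov, D = 5, substrate = "EX_S")
  expect_equal(low$status, "optimal")
  expect_equal(low$fluxes[["EX_S"]], 0.5, tolerance = 1e-5)
  expect_equal(low$fluxes[["EX_B"]], 0, tolerance = 1e-4)
  high <- chemostat(ov, D = 15, substrate = "EX_S")
  expect_equal(high$fluxes[["EX_S"]], 5.5, tolerance = 1e-4)
  expect_equal(high$fluxes[["EX_B"]], 5, tolerance = 1e-4)
  # above the maximum rate the stage is reported infeasible
  expect_equal(chemostat(ov, D = 25, substrate = "EX_S")$status,
               "infeasible")
  # D = 0: the all-zero solution
  zero <- chemostat(ov, D = 0, substrate = "EX_S")
  expect_equal(max(abs(zero$fluxes)), 0, tolerance = 1e-6)
})

test_that("batch growth is pool-limited and scales with the pool", {
  ov <- make_overflow_model(U = 100)
  r <- batch(ov, medium = c(EX_S = Inf), substrate = "EX_S")
  expect_equal(r$fluxes[["GROWTH"]], 20, tolerance = 1e-4)
  # doubling the pool doubles the maximum growth (LP homogeneity)
  ov2 <- make_overflow_model(U = 100, pool_size = 20)
  r2 <- batch(ov2, medium = c(EX_S = Inf), substrate = "EX_S")
  expect_equal(r2$fluxes[["GROWTH"]], 40, tolerance = 1e-3)
  # closing the medium stops growth
  r0 <- batch(ov, medium = c(EX_S = 0))
  expect_equal(r0$fluxes[["GROWTH"]], 0, tolerance = 1e-6)
  # without any abundance constraint batch refuses to run
  expect_error(batch(make_toy_ec()), "abundance constraint")
})

test_that("knockouts follow the gene rule semantics", {
  ec <- make_toy_ec()
  expect_equal(fba(knockout(ec, "P1"))$objective, 0, tolerance = 1e-9)
  # isozyme rescue: P2B alone is dispensable
  expect_equal(fba(knockout(ec, "P2B"))$objective, 10, tolerance = 1e-6)
  # one subunit blocks the whole complex reaction
  r <- fba(knockout(ec, "P3A"))
  expect_equal(r$fluxes[["R3"]], 0, tolerance = 1e-9)
  expect_error(knockout(ec, "NOPE"), "unknown enzyme")
})

test_that("yield envelopes trade growth against product", {
  ov <- make_overflow_model(U = 2)
  ye <- yield_envelope(ov, product = "EX_B", substrate = "EX_S", n = 5)
  expect_equal(nrow(ye), 5)
  expect_equal(ye$growth[5], 100 / 9, tolerance = 1e-4)
  # at zero growth no ATP may be made, so no fermentation byproduct
  expect_equal(ye$product_rate[1], 0, tolerance = 1e-6)
  # closed form: max byproduct at growth g is min(g/2, (20 - g)/8)
  expect_equal(ye$product_rate,
               pmin(ye$growth / 2, (20 - ye$growth) / 8),
               tolerance = 1e-4)
  expect_equal(ye$product_rate[5], 10 / 9, tolerance = 1e-4)
  # n = 2 returns exactly the two corners
  corners <- yield_envelope(ov, "EX_B", "EX_S", n = 2)
  expect_equal(corners$fraction, c(0, 1))
  # enzyme constraints only shrink the envelope relative to the
  # unconstrained network
  plain <- strip_enzymes(ov)
  for (i in seq_len(nrow(ye))) {
    m <- plain
    m <- set_bounds(m, "EX_S", lb = 2 * (1 - 1e-6), ub = 2)
    m <- set_bounds(m, "GROWTH", lb = ye$growth[i] * (1 - 1e-6))
    lp <- solve_lp(m, stats::setNames(1, "EX_B"), "max")
    expect_gte(lp$value + 1e-5, ye$product_rate[i])
  }
})

test_that("FVA of the unconstrained expansion equals the original model", {
  toy <- make_toy_gem()
  ec <- make_toy_ec()
  f0 <- fva(toy$model, fraction_of_optimum = 0)
  f1 <- fva(ec, fraction_of_optimum = 0)
  f1 <- f1[match(f0$reaction, f1$reaction), ]
  expect_equal(f1$min, f0$min, tolerance = 1e-9)
  expect_equal(f1$max, f0$max, tolerance = 1e-9)
  # at the growth optimum too
  g0 <- fva(toy$model, fraction_of_optimum = 1)
  g1 <- fva(ec, fraction_of_optimum = 1)
  g1 <- g1[match(g0$reaction, g1$reaction), ]
  expect_equal(g1$min, g0$min, tolerance = 1e-6)
  expect_equal(g1$max, g0$max, tolerance = 1e-6)
})

test_that("enzyme bounds shrink FVA ranges, never grow them", {
  toy <- make_toy_gem()
  ec <- make_toy_ec()
  f0 <- fva(toy$model, fraction_of_optimum = 0)
  set.seed(101)
  for (draw in 1:20) {
    eci <- ec
    for (p in c("P1", "P2A", "P2B", "P3A", "P3B")) {
      eci <- set_bounds(eci, paste0("draw_prot_", p),
                        ub = 10^runif(1, -5, -1))
    }
    fi <- fva(eci, fraction_of_optimum = 0)
    fi <- fi[match(f0$reaction, fi$reaction), ]
    expect_true(all(fi$min >= f0$min - 1e-9))
    expect_true(all(fi$max <= f0$max + 1e-9))
  }
})

test_that("a blocked enzyme collapses its reaction's range only in the expansion", {
  toy <- make_toy_gem()
  ec <- set_bounds(set_bounds(make_toy_ec(), "draw_prot_P2A", ub = 0),
                   "draw_prot_P2B", ub = 0)
  cmp <- compare_fva(toy$model, ec, fraction_of_optimum = 0)
  r2 <- cmp[cmp$reaction == "R2", ]
  expect_equal(r2$range_ec, 0, tolerance = 1e-9)
  expect_gt(r2$range_original, 1)
  expect_equal(r2$change, "reduced")
  expect_true(all(cmp$change != "increased"))
})

test_that("flux control concentrates on the active pathway and sums to one", {
  ov <- make_overflow_model(U = 100)  # pool is the unique binding constraint
  fcc <- flux_control_coefficients(ov, "GROWTH", delta = 1e-3)
  expect_equal(sum(fcc$fcc), 1, tolerance = 2e-3)
  expect_equal(fcc$fcc[fcc$protein_id == "ER"], 0, tolerance = 1e-9)
  expect_equal(fcc$fcc[fcc$protein_id == "EF"], 1, tolerance = 2e-3)
  # local linearity: doubling delta barely moves the coefficients
  fcc2 <- flux_control_coefficients(ov, "GROWTH", delta = 2e-3)
  expect_lt(max(abs(fcc2$fcc - fcc$fcc)), 1e-2)
  # a zero-flux target is refused with guidance
  ov0 <- set_bounds(ov, "EX_S", ub = 0)
  expect_error(flux_control_coefficients(ov0, "GROWTH"), "no flux")
})

test_that("saturation fitting recovers sigma = 1/2 for a halved target", {
  ov <- make_overflow_model(U = 100)
  mu_max <- fba(ov)$objective
  fit <- fit_sigma(ov, target = mu_max / 2)
  expect_true(fit$converged)
  expect_equal(fit$sigma, 0.5, tolerance = 1e-4)
  # growth is linear in sigma here, so the fit is essentially exact
  expect_equal(fit$value, mu_max / 2, tolerance = 1e-4)
  expect_error(fit_sigma(ov, target = 2 * mu_max), "unreachable")
  expect_warning(fit_sigma(ov, target = 0), "boundary")
})

test_that("recipes are deterministic across reruns", {
  ov <- make_overflow_model(U = 2)
  a <- chemostat(ov, D = 5, substrate = "EX_S")
  b <- chemostat(ov, D = 5, substrate = "EX_S")
  expect_identical(a$fluxes, b$fluxes)
  expect_identical(fba(ov)$fluxes, fba(ov)$fluxes)
})
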