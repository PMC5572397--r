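test_that("pool arithmetic bounds a single enzyme's usage", {
  # sigma = 1, f = 1, ptot = 10, one enzyme of 5 g/mmol -> max usage 2
  mets <- met_df(c("A", "B"))
  rx <- rxn_df(c("EX", "R", "OUT"), lb = 0, ub = c(1000, 1000, 1000),
               rule = c("", "G1", ""),
               stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1)))
  m <- metabolic_model(mets, rx, list(reaction = "OUT", direction = "max"))
  enz <- enzyme_table("P1", "G1", 5, "1.1.1.1")
  kin <- data.frame(ec = "1.1.1.1", substrate = "A", organism = "o",
                    kcat_per_s = 1 / 3600)  # kcat_h = 1: flux == usage
  ec <- expand_model(m, enz, assign_kcats(m, enz, kin, "o"))
  ec <- add_pool(ec, pool_config(ptot = 10, f = 1, sigma = 1))
  r <- fba(ec)
  expect_equal(r$usages[["P1"]], 2, tolerance = 1e-6)
  expect_equal(r$objective, 2, tolerance = 1e-6)
})

test_that("pooled optima respect and saturate the mass bound", {
  ec <- add_pool(make_toy_ec(), pool_config(ptot = 0.05, f = 1, sigma = 1))
  r <- fba(ec)
  expect_equal(r$status, "optimal")
  expect_lte(r$pool_usage, 0.05 * (1 + 1e-6))
  # the pool binds: growth below the uptake-limited optimum of 10
  expect_lt(r$objective, 10)
  # homogeneity: doubling sigma from 0.5 doubles growth while binding
  half <- fba(set_pool_sigma(add_pool(make_toy_ec(),
                                      pool_config(0.05, 1, 1)), 0.5))
  expect_equal(r$objective, 2 * half$objective, tolerance = 1e-5)
})

test_that("the pool bound never decreases growth when relaxed", {
  base <- make_toy_ec()
  mu <- vapply(c(0.01, 0.02, 0.05, 0.2),
               function(p) fba(add_pool(base, pool_config(p, 1, 1)))$objective,
               numeric(1))
  expect_true(all(diff(mu) >= -1e-9))
  expect_lte(mu[length(mu)], 10 + 1e-6)
})

test_that("pool guards: double pooling, empty scope, unknown enzymes", {
  ec <- make_toy_ec()
  pooled <- add_pool(ec, pool_config(0.1, 1, 1))
  expect_error(add_pool(pooled, pool_config(0.1, 1, 1)), "already has")
  expect_warning(add_pool(ec, pool_config(0.1, 1, 1), scope = character(0)),
                 "empty pool scope")
  expect_error(add_pool(ec, pool_config(0.1, 1, 1), scope = "NOPE"),
               "unknown enzyme")
  expect_error(pool_config(ptot = 0.448, f = 1.2), "f must be")
  expect_error(pool_config(ptot = 0.448, sigma = 0), "sigma must be")
})

test_that("proteomics bounds apply mean + sd and report matched mass", {
  ec <- make_toy_ec()
  ab <- matrix(c(2e-6, 2e-6, 2e-6,
                 1.5e-6, 2e-6, 2.5e-6), nrow = 2, byrow = TRUE,
               dimnames = list(c("P2A", "P1"), NULL))
  ps <- proteomics_set(ab, total_protein = 0.448)
  res <- set_proteomics_bounds(ec, ps)
  ub <- function(p) res$model$reactions$ub[
    match(paste0("draw_prot_", p), res$model$reactions$id)]
  expect_equal(ub("P2A"), 2e-6)            # sd 0
  expect_equal(ub("P1"), 2e-6 + sd(c(1.5e-6, 2e-6, 2.5e-6)))
  expect_equal(res$matched_mass, 50 * 2e-6 + 40 * 2e-6)
  expect_setequal(res$unmeasured, c("P2B", "P3A", "P3B"))
  # an all-zero measurement acts as a knockout
  ps0 <- proteomics_set(matrix(0, 1, 3, dimnames = list("P1", NULL)), 0.448)
  m0 <- set_proteomics_bounds(ec, ps0)$model
  expect_equal(fba(m0)$objective, 0, tolerance = 1e-9)
})

test_that("hybrid constraints split measured and pooled enzymes", {
  ec <- make_toy_ec()
  ps <- proteomics_set(matrix(5e-5, 1, 3, dimnames = list("P2A", NULL)),
                       total_protein = 0.448)
  h <- hybrid_constraints(ec, ps, f_unmeasured = 0.2154, sigma = 0.46)
  expect_equal(h$reactions$ub[match("draw_prot_P2A", h$reactions$id)], 5e-5)
  expect_setequal(h$pool$scope, c("P1", "P2B", "P3A", "P3B"))
  rep <- attr(h, "mass_report")
  matched <- 50 * 5e-5
  expect_equal(rep$remaining_mass, 0.448 - matched)
  expect_equal(h$pool$bound, 0.46 * 0.2154 * (0.448 - matched))
  # an over-full matched mass is an error
  ps_big <- proteomics_set(matrix(1, 1, 3, dimnames = list("P2A", NULL)),
                           total_protein = 0.448)
  expect_error(hybrid_constraints(ec, ps_big), "not below")
})

test_that("hybrid reduces to a plain pool with no measurements", {
  ec <- make_toy_ec()
  ps <- suppressWarnings(proteomics_set(
    matrix(1e-6, 1, 3, dimnames = list("NOT_IN_MODEL", NULL)), 0.448))
  h <- suppressWarnings(hybrid_constraints(ec, ps, f_unmeasured = 0.3,
                                           sigma = 0.5))
  direct <- add_pool(ec, pool_config(0.448, 0.3, 0.5))
  expect_equal(h$pool$bound, direct$pool$bound)
  expect_setequal(h$pool$scope, direct$pool$scope)
  expect_equal(fba(h)$objective, fba(direct)$objective, tolerance = 1e-9)
})

test_that("mass bookkeeping reproduces the reference integration numbers", {
  rep <- proteomics_mass_report(ptot = 0.448, matched_mass = 0.283,
                                f_unmeasured = 0.2154, sigma = 0.46)
  expect_equal(rep$remaining_mass, 0.165)
  expect_equal(round(rep$pool_mass, 3), 0.036)
  expect_equal(rep$matched_fraction_pct, 88.7, tolerance = 0.005)
})

test_that("complex abundances are corrected toward proportionality", {
  enz <- enzyme_table(c("PA", "PB"), c("gA", "gB"), c(10, 10),
                      c("1.1.1.1", "1.1.1.1"), complex_id = "CP",
                      stoich = c(1, 1))
  ps <- proteomics_set(matrix(c(2e-6, 2e-6, 4e-6, 4e-6), nrow = 2,
                              byrow = TRUE,
                              dimnames = list(c("PA", "PB"), NULL)), 0.448)
  out <- correct_complex_abundances(ps, enz)
  expect_equal(out$data$mean, c(3e-6, 3e-6))
  # already proportional stoich (1,2) with mu (3,6): unchanged
  enz2 <- enzyme_table(c("PA", "PB"), c("gA", "gB"), c(10, 10),
                       c("1.1.1.1", "1.1.1.1"), complex_id = "CP",
                       stoich = c(1, 2))
  ps2 <- proteomics_set(matrix(c(3e-6, 3e-6, 6e-6, 6e-6), nrow = 2,
                               byrow = TRUE,
                               dimnames = list(c("PA", "PB"), NULL)), 0.448)
  out2 <- correct_complex_abundances(ps2, enz2)
  expect_equal(out2$data$mean, c(3e-6, 6e-6))
  # single-subunit complex untouched
  enz3 <- enzyme_table("PA", "gA", 10, "1.1.1.1", complex_id = "CP")
  out3 <- correct_complex_abundances(ps, enz3)
  expect_equal(out3$data$mean[out3$data$protein_id == "PA"], 2e-6)
  # unmeasured complex warns
  enz4 <- enzyme_table(c("PX", "PY"), c("gX", "gY"), c(10, 10),
                       c("1.1.1.1", "1.1.1.1"), complex_id = "CQ")
  expect_warning(correct_complex_abundances(ps, enz4), "no measured subunit")
})

test_that("maintenance rewrites the ATP term and the NGAM bound", {
  mets <- met_df(c("atp", "adp", "pi", "h2o", "X"))
  rx <- rxn_df(c("BIO", "NGAM", "EX"), lb = 0, ub = 1000,
               stoich = list(c(atp = -20, h2o = -20, adp = 20, pi = 20,
                               X = -1),
                             c(atp = -1, h2o = -1, adp = 1, pi = 1),
                             c(X = 1)))
  m <- metabolic_model(mets, rx, list(reaction = "BIO", direction = "max"))
  m2 <- apply_maintenance(m, gam = 31, ngam = 0.7)
  st <- m2$reactions$stoich[[1]]
  expect_equal(st[["atp"]], -31)
  expect_equal(st[["adp"]], 31)
  expect_equal(st[["X"]], -1)  # non-maintenance terms untouched
  expect_equal(m2$reactions$lb[2], 0.7)
  # anaerobic value just rewrites the magnitude
  expect_equal(apply_maintenance(m, 16, 0)$reactions$stoich[[1]][["atp"]],
               -16)
  # a biomass without ATP is refused
  m_bad <- metabolic_model(mets, rxn_df("BIO", 0, 10,
                                        stoich = list(c(X = -1))),
                           list(reaction = "BIO", direction = "max"))
  expect_error(apply_maintenance(m_bad, 31, 0.7, ngam_rxn = "BIO"),
               "no ATP hydrolysis")
})

test_that("raising NGAM never increases achievable growth", {
  mets <- met_df(c("S", "ATP"))
  rx <- rxn_df(c("EX_S", "CAT", "NGAM", "GROWTH"), lb = 0,
               ub = c(10, 1000, 1000, 1000),
               stoich = list(c(S = 1), c(S = -1, ATP = 2), c(ATP = -1),
                             c(ATP = -1)))
  m <- metabolic_model(mets, rx, list(reaction = "GROWTH",
                                      direction = "max"))
  mus <- vapply(c(0, 5, 10, 20), function(ng)
    fba(set_bounds(m, "NGAM", lb = ng))$objective, numeric(1))
  expect_true(all(diff(mus) <= 1e-9))
})
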