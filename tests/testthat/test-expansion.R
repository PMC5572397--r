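test_that("reversible splitting produces forward/backward pairs", {
  mets <- met_df(c("A", "B"))
  rx <- rxn_df(c("R1", "R2", "R3"), lb = c(-5, 0, -7), ub = c(10, 1000, 0),
               stoich = list(c(A = -1, B = 1), c(A = -1, B = 1),
                             c(A = -1, B = 1)))
  m <- split_reversible(metabolic_model(mets, rx))
  expect_setequal(m$reactions$id, c("R1", "R1_REV", "R2", "R3_REV"))
  i <- match("R1", m$reactions$id)
  expect_equal(m$reactions$lb[i], 0)
  expect_equal(m$reactions$ub[i], 10)
  j <- match("R1_REV", m$reactions$id)
  expect_equal(m$reactions$ub[j], 5)
  expect_equal(m$reactions$stoich[[j]], c(A = 1, B = -1))
  # irreversible untouched
  expect_equal(m$reactions$ub[match("R2", m$reactions$id)], 1000)
  # pure-backward flipped
  k <- match("R3_REV", m$reactions$id)
  expect_equal(m$reactions$lb[k], 0)
  expect_equal(m$reactions$ub[k], 7)
  expect_equal(m$reactions$stoich[[k]], c(A = 1, B = -1))
})

test_that("toy model splits 6 reactions into 7", {
  toy <- make_toy_gem()
  expect_equal(nrow(split_reversible(toy$model)$reactions), 7)
})

test_that("isozyme OR rules get an arm reaction and ordered copies", {
  toy <- make_toy_gem()
  m <- expand_isozymes(split_reversible(toy$model), toy$enzymes)
  expect_true(all(c("arm_R2", "R2No1", "R2No2") %in% m$reactions$id))
  expect_false("R2" %in% m$reactions$id)
  expect_true("pmet_R2" %in% m$metabolites$id)
  # arm keeps original bounds and carries substrates into the pseudo-met
  arm <- m$reactions[m$reactions$id == "arm_R2", ]
  expect_equal(arm$ub, 1000)
  expect_equal(arm$stoich[[1]], c(B = -1, pmet_R2 = 1))
  # copies ordered by sorted protein id: P2A before P2B
  expect_equal(m$reactions$gene_rule[m$reactions$id == "R2No1"], "GP2A")
  expect_equal(m$reactions$gene_rule[m$reactions$id == "R2No2"], "GP2B")
  # AND-only rule gets no arm
  expect_true("R3" %in% m$reactions$id)
  expect_false("arm_R3" %in% m$reactions$id)
})

test_that("a mixed OR-of-AND rule yields one complex and one single copy", {
  mets <- met_df(c("X", "Y"))
  rx <- rxn_df("R", 0, 10, rule = "(GA and GB) or GC",
               stoich = list(c(X = -1, Y = 1)))
  enz <- enzyme_table(c("PA", "PB", "PC"), c("GA", "GB", "GC"), 10,
                      c("1.1.1.1", "1.1.1.1", "1.1.1.2"))
  m <- expand_isozymes(split_reversible(metabolic_model(mets, rx)), enz)
  copies <- grep("^RNo", m$reactions$id, value = TRUE)
  expect_length(copies, 2)
  rules <- m$reactions$gene_rule[match(copies, m$reactions$id)]
  expect_setequal(gene_rule_dnf(paste0("(", rules[1], ") or (", rules[2],
                                       ")")),
                  list(c("GA", "GB"), "GC"))
})

test_that("kinetic coefficients follow -stoich/kcat_h", {
  ec <- make_toy_ec()
  st1 <- ec$reactions$stoich[[match("R1", ec$reactions$id)]]
  expect_equal(st1[["prot_P1"]], -1 / 36000)  # 10/s * 3600
  st3 <- ec$reactions$stoich[[match("R3", ec$reactions$id)]]
  expect_equal(st3[["prot_P3A"]], -1 / 7200)  # 2/s, stoich 1
  expect_equal(st3[["prot_P3B"]], -2 / 7200)  # 2/s, stoich 2
  # promiscuous enzyme: same row, two columns, different kcats
  st4 <- ec$reactions$stoich[[match("R4", ec$reactions$id)]]
  expect_equal(st4[["prot_P2A"]], -1 / 3600)  # curated 1/s
  st2 <- ec$reactions$stoich[[match("R2No1", ec$reactions$id)]]
  expect_equal(st2[["prot_P2A"]], -1 / 72000)
})

test_that("full expansion of the toy model has the expected shape", {
  ec <- make_toy_ec()
  expect_equal(nrow(ec$reactions), 14)
  expect_equal(nrow(ec$metabolites), 10)
  expect_length(grep("^draw_prot_", ec$reactions$id), 5)
  expect_silent(validate_ec_model(ec))
})

test_that("expansion is rejected on an already expanded model", {
  toy <- make_toy_gem()
  asg <- assign_kcats(toy$model, toy$enzymes, toy$kinetics, toy$organism)
  ec <- make_toy_ec()
  expect_error(expand_model(ec, toy$enzymes, asg), "expansion markers")
  expect_error(attach_enzymes(ec, asg, toy$enzymes), "already")
})

test_that("missing kcat assignments are reported as pairs", {
  toy <- make_toy_gem()
  asg <- assign_kcats(toy$model, toy$enzymes, toy$kinetics, toy$organism)
  expect_error(expand_model(toy$model, toy$enzymes,
                            asg[asg$rxn_id != "R3", ]),
               "missing kcat assignment.*R3")
})

test_that("an enzyme-free model expands to its split form", {
  mets <- met_df(c("A", "B"))
  rx <- rxn_df(c("EX", "R", "OUT"), lb = c(0, -5, 0), ub = c(10, 10, 100),
               stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1)))
  m <- metabolic_model(mets, rx, list(reaction = "OUT", direction = "max"))
  enz <- enzyme_table(character(0), character(0), numeric(0), list())
  ec <- expand_model(m, enz, assign_kcats(m, enz, data.frame(
    ec = "1.1.1.1", substrate = "x", organism = "y", kcat_per_s = 1), "y"))
  split <- split_reversible(m)
  expect_setequal(ec$reactions$id, split$reactions$id)
  expect_equal(fba(ec)$objective, fba(m)$objective)
})

test_that("stripping the expansion recovers the original model", {
  toy <- make_toy_gem()
  ec <- make_toy_ec()
  back <- strip_enzymes(ec)
  S0 <- stoich_matrix(toy$model)
  S1 <- stoich_matrix(back)[rownames(S0), colnames(S0)]
  expect_equal(S1, S0, tolerance = 1e-12)
  ord <- match(toy$model$reactions$id, back$reactions$id)
  expect_equal(back$reactions$lb[ord], toy$model$reactions$lb)
  expect_equal(back$reactions$ub[ord], toy$model$reactions$ub)
  for (i in seq_along(ord)) {
    expect_equal(gene_rule_dnf(back$reactions$gene_rule[ord[i]]),
                 gene_rule_dnf(toy$model$reactions$gene_rule[i]))
  }
})

test_that("classification partitions the model and spots relationships", {
  ec <- make_toy_ec()
  cls <- classify_model(ec)
  get <- function(cat, cl) cls$count[cls$category == cat & cls$class == cl]
  expect_equal(get("reactions", "arm"), 1)
  expect_equal(get("reactions", "usage"), 5)
  expect_equal(get("reactions", "exchange"), 2)  # EX_A and GROWTH drain
  expect_equal(get("relationships", "complexes"), 1)
  expect_equal(get("relationships", "isozyme_reactions"), 1)
  expect_equal(get("relationships", "promiscuous_enzymes"), 1)
  tot <- summarize_descriptors(cls)
  expect_equal(tot$reactions, nrow(ec$reactions))
  expect_equal(tot$metabolites, nrow(ec$metabolites))
})

test_that("published yeast descriptor sums reproduce the model totals", {
  desc <- ecyeast7_descriptors()
  tot <- summarize_descriptors(desc)
  expect_equal(tot$reactions, 6741)
  expect_equal(tot$metabolites, 3388)
})
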