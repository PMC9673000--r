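test_that("the schema enumerations have the documented shape", {
  nk <- node_kinds()
  expect_setequal(nk$code, c("P", "H", "S", "O", "CD", "E", "D", "C"))
  expect_length(nk$code, 8)

  expect_length(outcome_levels(), 5)

  rk <- relation_kinds()
  expect_length(unique(rk$code), 9)
  # spot-check endpoint signatures
  expect_equal(rk[rk$code == "With", c("source_kind", "target_kind")],
               data.frame(source_kind = "P", target_kind = "CD"),
               ignore_attr = TRUE)
  expect_equal(rk[rk$code == "Order", c("source_kind", "target_kind")],
               data.frame(source_kind = "E", target_kind = "E"),
               ignore_attr = TRUE)
  expect_equal(nrow(rk[rk$code == "Sue", ]), 2)

  reg <- error_registry()
  expect_gte(nrow(reg), 20)
  expect_false(anyDuplicated(reg$label) > 0)
  expect_type(reg$technical, "logical")
  expect_false(reg$technical[reg$label == "inadequate informed consent"])
  expect_true(reg$technical[reg$label == "delay in treatment"])
  ext <- error_registry(extra = data.frame(label = "wrong-site surgery",
                                           technical = TRUE))
  expect_equal(nrow(ext), nrow(reg) + 1)
  expect_error(error_registry(extra = reg[1, ]), "duplicated")
})

test_that("validate_graph flags every class of schema violation", {
  expect_equal(nrow(validate_graph(malpractice_graph())), 0)

  # endpoint-kind mismatch: an Order edge from E to D
  g <- mk_graph(c("e1", "d1"), cbind("e1", "d1"),
                kinds = c("E", "D"), relations = "Order")
  g$nodes$label <- c("delay in treatment", "d1")
  rep <- validate_graph(g)
  expect_equal(rep$rule, "endpoint_kind_mismatch")

  # dangling edge
  g <- mk_graph("a", cbind("a", "ghost"))
  expect_equal(validate_graph(g)$rule, "dangling_edge")

  # unknown node kind
  g <- mk_graph("a", matrix(character(), 0, 2), kinds = "X")
  expect_equal(validate_graph(g)$rule, "unknown_node_kind")

  # outcome and error vocabulary
  g <- malpractice_graph(
    data.frame(id = c("o1", "e1"), kind = c("O", "E"),
               label = c("vaporized", "made-up error")),
    data.frame(from = character(), to = character()))
  expect_setequal(validate_graph(g)$rule,
                  c("outcome_vocabulary", "error_vocabulary"))

  # Order cycle within one case
  labs <- error_registry()$label[1:3]
  g <- malpractice_graph(
    data.frame(id = labs, kind = "E", label = labs),
    data.frame(from = labs, to = labs[c(2, 3, 1)], relation = "Order",
               case = "C1"))
  expect_true("order_chain" %in% validate_graph(g)$rule)
  # the same edges as an open chain are fine
  g$edges <- g$edges[1:2, ]
  expect_equal(nrow(validate_graph(g)), 0)
})

test_that("validation is idempotent and order-independent", {
  g <- generate_mmnc(mmnc_gen_params(n_cases = 40, seed = 3))
  r1 <- validate_graph(g)
  perm <- withr::with_seed(1, sample(nrow(g$edges)))
  g2 <- malpractice_graph(g$nodes, g$edges[perm, ])
  expect_identical(r1, validate_graph(g2))
  expect_identical(validate_graph(g), r1)
})

test_that("case cardinality checks hold for a complete case and fail when links are removed", {
  cs <- list(list(case = "C1", patient = "P1", hospital = "H1",
                  specialty = "S1", disease = "D1",
                  comorbidities = "CD1", outcome = "death",
                  errors = c("delay in treatment",
                             "inadequate informed consent")))
  g <- graph_from_cases(cs)
  expect_equal(nrow(validate_graph(g)), 0)
  expect_true(all(case_cardinality_checks(g)))
  expect_equal(sum(g$edges$relation == "Sue"), 2)
  expect_equal(sum(g$edges$relation == "Cause"), 1)
  expect_equal(sum(g$edges$relation == "Error"), 1)
  expect_equal(sum(g$edges$relation == "Order"), 1)

  # deleting the Cause link breaks the errorful-case identity
  g2 <- g
  g2$edges <- g2$edges[g2$edges$relation != "Cause", ]
  chk <- case_cardinality_checks(g2)
  expect_false(chk[["cause_matches_errorful"]])
  expect_true(chk[["two_sue_per_case"]])

  # a third Sue link breaks (a)
  g3 <- g
  g3$edges <- rbind(g3$edges,
                    data.frame(from = "P1", to = "H1", relation = "Sue",
                               case = "C1"))
  expect_false(case_cardinality_checks(g3)[["two_sue_per_case"]])
})

test_that("published corpus tallies are internally consistent", {
  rc <- mmnc_reported_counts()
  expect_equal(sum(rc$node_counts), unname(rc$reported["total_nodes"]))
  expect_equal(sum(rc$relation_counts),
               unname(rc$reported["total_relationships"]))
})
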