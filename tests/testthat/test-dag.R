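test_that("edge-list parsing builds validated DAGs and rejects bad input", {
  d <- parse_dag("A -> B\nB -> C")
  expect_s3_class(d, "causal_dag")
  expect_equal(length(d$nodes), 3L)
  expect_equal(nrow(d$edges), 2L)

  expect_error(parse_dag("A -> B\nB -> A"), "cycle")
  expect_error(parse_dag("A -> A"), "self-loop")
  expect_error(parse_dag("A -> B\nA -> B"), "duplicate edge")
  expect_error(parse_dag("A -> "), "cannot parse")

  # comments, blank lines, latent and isolated-node declarations
  d2 <- parse_dag("# model\nlatent: U\nU -> X\nU -> Y  # fork\nnode: W\n")
  expect_setequal(d2$nodes, c("U", "X", "Y", "W"))
  expect_equal(d2$latent, "U")
  expect_error(parse_dag("latent: Q\nA -> B"), "unknown node")
})

test_that("the pinned study DAG has the documented structure", {
  d <- study_dag()
  expect_equal(length(d$nodes), 12L)
  expect_equal(length(d$observed), 11L)
  expect_equal(d$latent, "BrainInjury")
  expect_equal(nrow(d$edges), 45L)
  # walking speed only affects gait pattern and power
  expect_setequal(dag_children(d, "Speed"), c("GDI", "MetPower"))
})

test_that("d-separation follows the chain, fork and collider rules", {
  chain <- parse_dag("A -> B\nB -> C")
  expect_true(d_separated(chain, "A", "C", "B"))
  expect_false(d_separated(chain, "A", "C"))

  collider <- parse_dag("A -> C\nB -> C")
  expect_true(d_separated(collider, "A", "B"))
  expect_false(d_separated(collider, "A", "B", "C"))
  # conditioning on a collider's descendant also opens the path
  cd <- parse_dag("A -> C\nB -> C\nC -> D")
  expect_false(d_separated(cd, "A", "B", "D"))

  d <- study_dag()
  expect_true(d_separated(d, "Sex", "MetPower", c("Age", "Height", "Mass")))
  expect_false(d_separated(d, "Sex", "MetPower", c("Age", "Height")))
  expect_error(d_separated(d, "Sex", "NoSuch"), "unknown variable")
})

test_that("d-separation is symmetric and agrees with the path-blocking oracle", {
  set.seed(401)
  for (rep in 1:50) {
    dag <- random_dag(sample(4:7, 1L))
    expect_identical(dsep_disagreements(dag), 0L)
    # symmetry spot-check on the same graph
    nodes <- dag$nodes
    pick <- sample(nodes, 2L)
    z <- setdiff(nodes, pick)
    z <- z[stats::runif(length(z)) < 0.4]
    expect_identical(d_separated(dag, pick[1L], pick[2L], z),
                     d_separated(dag, pick[2L], pick[1L], z))
  }
})

test_that("implied independencies carry minimal separating sets", {
  iso <- parse_dag("node: X\nnode: Y")
  st <- implied_independencies(iso)
  expect_length(st, 1L)
  expect_identical(st[[1L]]$given, character(0))

  chain <- parse_dag("A -> B\nB -> C")
  st <- implied_independencies(chain)
  expect_length(st, 1L)
  expect_identical(st[[1L]], list(x = "A", y = "C", given = "B"))

  d <- study_dag()
  st <- implied_independencies(d)
  keys <- vapply(st, function(s) paste(s$x, s$y), character(1L))
  expect_true("Age Sex" %in% keys)
  expect_identical(st[[which(keys == "Age Sex")]]$given, character(0))
  # every emitted statement must hold in the graph, with no removable member
  for (s in st) {
    expect_true(d_separated(d, s$x, s$y, s$given))
    for (g in s$given) {
      expect_false(d_separated(d, s$x, s$y, setdiff(s$given, g)))
    }
  }
  # impairment pairs share the latent brain injury: no observed separator
  expect_false(any(grepl("Spasticity", keys) & grepl("Strength", keys)))
})

test_that("minimal adjustment sets satisfy and minimally satisfy the backdoor criterion", {
  conf <- parse_dag("Z -> X\nZ -> Y\nX -> Y")
  a <- minimal_adjustment_sets(conf, "X", "Y")
  expect_true(a$identifiable)
  expect_identical(a$sets, list("Z"))

  plain <- parse_dag("X -> Y")
  expect_identical(minimal_adjustment_sets(plain, "X", "Y")$sets,
                   list(character(0)))

  hidden <- parse_dag("latent: U\nU -> X\nU -> Y\nX -> Y")
  h <- minimal_adjustment_sets(hidden, "X", "Y")
  expect_false(h$identifiable)
  expect_length(h$sets, 0L)
  expect_output(print(h), "not identifiable")

  # independent backdoor check on the study DAG: conditioning on a returned
  # set separates exposure from outcome once the exposure's outgoing edges
  # are removed, and dropping any single member reconnects them
  d <- study_dag()
  for (e in c("GDI", "DMC", "Spasticity")) {
    s <- minimal_adjustment_sets(d, e, "MetPower")$sets[[1L]]
    g <- d
    g$edges <- d$edges[d$edges[, 1L] != e, , drop = FALSE]
    expect_true(d_separated(g, e, "MetPower", s))
    for (m in s) {
      expect_false(d_separated(g, e, "MetPower", setdiff(s, m)))
    }
    expect_true(all(!s %in% dag_descendants(d, e)))
    expect_false("BrainInjury" %in% s)
  }
})

test_that("the study DAG reproduces the published adjustment sets exactly", {
  d <- study_dag()
  expected <- list(
    GDI = c("Speed", "DMC", "SMC", "Spasticity", "Strength",
            "Age", "Height", "Mass"),
    DMC = c("SMC", "Spasticity", "Strength", "Age", "Height", "Mass"),
    SMC = c("DMC", "Spasticity", "Strength", "Age", "Height", "Mass"),
    Spasticity = c("DMC", "SMC", "Strength", "Age", "Height", "Mass"),
    Strength = c("DMC", "SMC", "Spasticity", "Age", "Height", "Mass"))
  for (e in names(expected)) {
    a <- minimal_adjustment_sets(d, e, "MetPower")
    expect_length(a$sets, 1L)
    expect_setequal(a$sets[[1L]], expected[[e]])
  }
})
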