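test_that("the synchronous step reads every node from the current state", {
  tog <- fixture("toggle")
  expect_identical(unname(synchronous_step(tog, c(0L, 1L))), c(1L, 0L))
  expect_identical(unname(synchronous_step(tog, c(0L, 0L))), c(0L, 0L))

  neg <- fixture("negator")
  s1 <- synchronous_step(neg, 0L)
  expect_identical(unname(s1), 1L)
  expect_identical(unname(synchronous_step(neg, s1)), 0L)

  expect_error(synchronous_step(tog, c(0L, 1L, 0L)), class = "bn_domain_error")
  expect_error(synchronous_step(tog, c(0L, 2L)), class = "bn_domain_error")
})

test_that("exhaustive search finds the toggle's complete attractor landscape", {
  aset <- find_attractors(fixture("toggle"))
  expect_length(aset$attractors, 3L)
  lengths <- sort(vapply(aset$attractors, function(a) nrow(a$states), 0L))
  expect_identical(lengths, c(1L, 1L, 2L))
  expect_identical(sum(vapply(aset$attractors, `[[`, 0L, "basin_size")), 4L)

  # canonical rotation: the 2-cycle starts at its lexicographically
  # smallest state (0,1), then (1,0)
  cyc <- aset$attractors[[which(vapply(aset$attractors, function(a)
    nrow(a$states), 0L) == 2L)]]
  expect_identical(unname(cyc$states),
                   matrix(c(0L, 1L, 1L, 0L), nrow = 2, byrow = TRUE))
})

test_that("degenerate landscapes are handled: constants and oscillators", {
  const <- parse_boolnet("targets, factors\nA, 1\nB, 0\nC, A")
  aset <- find_attractors(const)
  expect_length(aset$attractors, 1L)
  expect_identical(unname(aset$attractors[[1]]$states[1, ]), c(1L, 0L, 1L))
  expect_identical(aset$attractors[[1]]$basin_size, 8L)

  neg <- find_attractors(fixture("negator"))
  expect_length(neg$attractors, 1L)
  expect_identical(nrow(neg$attractors[[1]]$states), 2L)

  big <- random_boolean_network(25, 2, seed = 1)
  expect_error(find_attractors(big), class = "bn_capacity_error")
})

test_that("attractors match explicit state-graph cycle detection on random networks", {
  for (seed in 1:50) {
    net <- random_boolean_network(4L + seed %% 5L, 1L + seed %% 3L,
                                  seed = 300L + seed)
    expect_identical(attractor_keys(find_attractors(net)),
                     oracle_attractors(net))
  }
})

test_that("every forward trajectory lands in a returned attractor", {
  for (seed in c(7, 21, 33)) {
    net <- random_boolean_network(6, 2, seed = 400L + seed)
    aset <- find_attractors(net)
    codes_in_attractors <- unlist(lapply(aset$attractors, `[[`, "codes"))
    n <- length(net$nodes)
    for (code in 0:(2^n - 1L)) {
      state <- as.integer(bitwAnd(bitwShiftR(code, seq_len(n) - 1L), 1L))
      for (step in seq_len(2^n + 2L)) {
        state <- unname(synchronous_step(net, state))
      }
      final_code <- sum(state * 2L^(seq_len(n) - 1L))
      expect_true(final_code %in% codes_in_attractors)
    }
  }
})

test_that("perturbations fix a node and are idempotent", {
  tog <- fixture("toggle")
  ko <- apply_perturbation(tog, "A", 0)
  expect_identical(ko$rules$A$inputs, character(0))
  expect_identical(ko$rules$A$table, 0L)
  expect_identical(ko$rules$B, tog$rules$B)
  oe <- apply_perturbation(tog, "A", 1)
  expect_identical(oe$rules$A$table, 1L)
  expect_identical(apply_perturbation(ko, "A", 0), ko)
  expect_error(apply_perturbation(tog, "Z", 0), class = "bn_domain_error")
  expect_error(apply_perturbation(tog, "A", 2), class = "bn_domain_error")

  # the perturbed node is constant in every attractor state
  for (seed in 1:10) {
    net <- random_boolean_network(6, 2, seed = 500L + seed)
    pert <- apply_perturbation(net, net$nodes[[1]], 1L)
    aset <- find_attractors(pert)
    for (a in aset$attractors) {
      expect_true(all(a$states[, 1] == 1L))
    }
  }
})

test_that("impact metrics match exhaustive enumeration on the pinned cases", {
  tog <- fixture("toggle")
  orig <- find_attractors(tog)
  same <- impact_metrics(orig, find_attractors(tog))
  expect_equal(same$fraction_lost, 0)
  expect_identical(same$n_new, 0L)

  # knockout of A collapses the landscape onto the (0,0) fixed point,
  # which was already an attractor: 2 of 3 originals lost, nothing new
  ko <- impact_metrics(orig, find_attractors(apply_perturbation(tog, "A", 0)))
  expect_equal(ko$fraction_lost, 2 / 3)
  expect_identical(ko$n_new, 0L)

  # overexpressing the self-inhibitor: the period-2 attractor {0, 1} is
  # replaced by the fixed point {1}; new as a set, but its state already
  # occurred, so the minimal Hamming distance is 0
  neg <- fixture("negator")
  oe <- impact_metrics(find_attractors(neg),
                       find_attractors(apply_perturbation(neg, "A", 1)))
  expect_equal(oe$fraction_lost, 1)
  expect_identical(oe$n_new, 1L)
  expect_identical(oe$min_hamming, 0L)

  other <- find_attractors(fixture("chain3"))
  expect_error(impact_metrics(orig, other), class = "bn_domain_error")
})

test_that("a genuinely novel attractor reports its Hamming gap", {
  # A,B copy constant source S; knocking S out moves the sole attractor
  # from (1,1,1) to (0,0,0): distance 3
  net <- parse_boolnet("targets, factors\nS, 1\nA, S\nB, S")
  orig <- find_attractors(net)
  pert <- find_attractors(apply_perturbation(net, "S", 0))
  metrics <- impact_metrics(orig, pert)
  expect_equal(metrics$fraction_lost, 1)
  expect_identical(metrics$n_new, 1L)
  expect_identical(metrics$min_hamming, 3L)
})

test_that("metrics are equivariant under node relabeling", {
  net <- random_boolean_network(5, 2, seed = 42)
  lines <- write_boolnet(net)
  relabeled <- lines
  for (i in seq_along(net$nodes)) {
    relabeled <- gsub(paste0("\\b", net$nodes[[i]], "\\b"),
                      sprintf("M%d_", i), relabeled)
  }
  net2 <- parse_boolnet(relabeled)
  m1 <- impact_metrics(find_attractors(net),
                       find_attractors(apply_perturbation(net, "N2", 0)))
  m2 <- impact_metrics(find_attractors(net2),
                       find_attractors(apply_perturbation(net2, "M2_", 0)))
  expect_equal(m1$fraction_lost, m2$fraction_lost)
  expect_identical(m1$n_new, m2$n_new)
  expect_identical(sort(m1$min_hamming), sort(m2$min_hamming))
})

test_that("attractor JSON export lists bit-strings in node order", {
  json <- attractors_to_json(find_attractors(fixture("toggle")))
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_identical(unlist(parsed$nodes), c("A", "B"))
  states <- lapply(parsed$attractors, function(a) unlist(a$states))
  expect_true(any(vapply(states, function(s) identical(s, c("01", "10")),
                         TRUE)))
})
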