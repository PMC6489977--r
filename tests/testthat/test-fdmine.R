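test_that("discovery on the worked example matches the brute-force oracle", {
  r <- example_relation()
  res <- run_fdmine(r)

  expect_true(all(c("A>D", "D>A") %in% fd_keys(res$fds)))
  eq_keys <- vapply(res$equivalences, function(e) {
    paste(sort(vapply(e, paste, character(1), collapse = ",")), collapse = "~")
  }, character(1))
  expect_true("A~D" %in% eq_keys)
  expect_same_sets(res$keys,
                   list(c("A", "B", "C"), c("B", "C", "D"), c("B", "C", "E")))

  # closure-completeness modulo equivalences, against the oracle
  oracle <- brute_force_minimal_fds(r)
  expect_true(closures_agree(r$attributes, result_fdset(res, r$attributes), oracle))

  # counters and flags
  expect_identical(res$fds_found, length(res$fds))
  expect_false(res$truncated)
  expect_identical(res$rows, 7L)
  expect_identical(res$attribute_count, 5L)
})

test_that("level-1 validation on the example finds exactly A->D and D->A", {
  r <- example_relation()
  singles <- lapply(as_attrset(r$attributes), identity)
  closures <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  state$universe <- as_attrset(r$attributes)
  state$fds <- list(); state$checked <- 0L; state$truncated <- FALSE
  state$cache <- NULL; state$deadline <- NULL
  fdminer:::obtain_fds(r, singles, closures, state)
  expect_identical(fd_keys(state$fds), c("A>D", "D>A"))
  expect_identical(state$checked, 5L)

  # and the level-1 equivalence scan records {A} <-> {D}
  state$equivalences <- list()
  state$deleted <- new.env(parent = emptyenv())
  fdminer:::obtain_equivalences(singles, closures, state)
  expect_length(state$equivalences, 1)
  expect_identical(sort(unlist(state$equivalences[[1]])), c("A", "D"))
  # the earlier-generated side is the one marked deleted
  expect_identical(ls(state$deleted), fdminer:::set_key("A"))
})

test_that("pruning removes supersets once a key is found (corrected lattice walk)", {
  # relation where {A,B} is a key and the oracle confirms no other minimal FDs
  rel <- NULL
  for (try in 1:50) {
    set.seed(6000 + try)
    grid <- expand.grid(A = sprintf("a%d", 1:6), B = sprintf("b%d", 1:6),
                        stringsAsFactors = FALSE)
    df <- data.frame(
      grid,
      C = sample(sprintf("c%d", 1:4), nrow(grid), replace = TRUE),
      D = sample(sprintf("d%d", 1:4), nrow(grid), replace = TRUE),
      E = sample(sprintf("e%d", 1:4), nrow(grid), replace = TRUE)
    )
    cand <- fd_relation(df, name = "ab_key")
    oracle <- brute_force_minimal_fds(cand)
    ok <- identical(fd_keys(oracle$fds),
                    fd_keys(list(fd(c("A", "B"), "C"), fd(c("A", "B"), "D"),
                                 fd(c("A", "B"), "E"))))
    if (ok) { rel <- cand; break }
  }
  expect_false(is.null(rel))

  res <- run_fdmine(rel)
  expect_same_sets(res$keys, list(c("A", "B")))
  # no non-minimal FD: nothing beyond the three AB -> x dependencies
  expect_identical(fd_keys(res$fds),
                   fd_keys(list(fd(c("A", "B"), "C"), fd(c("A", "B"), "D"),
                                fd(c("A", "B"), "E"))))
  for (f in res$fds) expect_lte(length(f$lhs), 2)
})

test_that("closure propagation resolves closures of never-generated sets", {
  closures <- new.env(parent = emptyenv())
  closures[[fdminer:::set_key("A")]] <- "D"
  closures[[fdminer:::set_key("B")]] <- character(0)
  expect_identical(fdminer:::closure_of_subset(c("A", "B"), closures), "D")
  expect_identical(fdminer:::closure_of_subset("Z", closures), character(0))
  # stored entries are returned as-is
  closures[[fdminer:::set_key(c("A", "B"))]] <- c("D", "E")
  expect_identical(fdminer:::closure_of_subset(c("A", "B"), closures), c("D", "E"))
})

test_that("discovered FDs are sound and minimal on random relations", {
  for (seed in 701:715) {
    rr <- random_relation(seed, n_attrs = sample(3:5, 1),
                          n_rows = sample(10:80, 1))$relation
    res <- run_fdmine(rr)
    agree <- fdminer:::pair_agreement(rr)
    keys <- fd_keys(res$fds)
    for (f in res$fds) {
      expect_true(fdminer:::pairwise_fd_holds(agree, f$lhs, f$rhs),
                  info = sprintf("seed %d: unsound %s", seed, format_fd(f)))
      # minimality among the recorded set
      for (g in res$fds) {
        if (identical(g$rhs, f$rhs) && length(g$lhs) < length(f$lhs)) {
          expect_false(all(g$lhs %in% f$lhs),
                       info = sprintf("seed %d: %s subsumed", seed, format_fd(f)))
        }
      }
    }
  }
})

test_that("results are deterministic and independent of row order", {
  rr <- random_relation(808, n_attrs = 5, n_rows = 60)$relation
  res1 <- run_fdmine(rr)
  set.seed(1)
  shuffled <- rr
  shuffled$data <- rr$data[sample(n_rows(rr)), , drop = FALSE]
  res2 <- run_fdmine(shuffled)
  expect_identical(fd_keys(res1$fds), fd_keys(res2$fds))
  expect_same_sets(res1$keys, res2$keys)
  expect_identical(res1$candidates_checked, res2$candidates_checked)
})

test_that("termination bounds hold: at most |U| levels, checked <= 2^|U| - 1", {
  for (seed in 901:906) {
    rr <- random_relation(seed)$relation
    res <- run_fdmine(rr)
    expect_lte(res$candidates_checked, 2^n_attributes(rr) - 1)
    expect_false(res$truncated)
  }
})

test_that("degenerate relations are handled", {
  # single attribute, distinct values: the attribute is the key
  r1 <- fd_relation(data.frame(A = c("1", "2", "3")))
  res1 <- run_fdmine(r1)
  expect_length(res1$fds, 0)
  expect_same_sets(res1$keys, list("A"))
  expect_identical(res1$candidates_checked, 1L)

  # single attribute with duplicates: no key at all
  r2 <- fd_relation(data.frame(A = c("1", "1", "2")))
  expect_length(run_fdmine(r2)$keys, 0)

  # duplicate full rows defeat every key
  r3 <- fd_relation(data.frame(A = c(1, 1), B = c(2, 2)))
  expect_length(run_fdmine(r3)$keys, 0)
  expect_length(brute_force_keys(r3), 0)

  # zero attributes is an input error
  expect_error(run_fdmine(fd_relation(data.frame()[0, 0, drop = FALSE])),
               "no attribute")
})

test_that("the time limit truncates the search and flags the result", {
  set.seed(42)
  wide <- fd_relation(as.data.frame(matrix(sample(0:9, 10 * 300, replace = TRUE),
                                           ncol = 10,
                                           dimnames = list(NULL, LETTERS[1:10]))))
  res <- run_fdmine(wide, time_limit_seconds = 1e-6)
  expect_true(res$truncated)
  expect_lt(res$candidates_checked, 2^10 - 1)
})
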