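test_that("dwelling fractions round to the nearest 5% tone", {
  expect_equal(bin_dwelling_fraction(1.0), 20L)   # the pure-red 100% tone
  expect_equal(bin_dwelling_fraction(0.0), 0L)
  expect_equal(bin_dwelling_fraction(0.52), 10L)  # 50% tone
  expect_equal(bin_dwelling_fraction(0.53), 11L)
  expect_equal(bin_dwelling_fraction(0.025), 0L)  # upper edge of bin 0
  expect_equal(bin_dwelling_fraction(0.0251), 1L)
  expect_equal(bin_dwelling_fraction(0.975), 19L)
  expect_equal(bin_dwelling_fraction(0.9751), 20L)
  expect_error(bin_dwelling_fraction(1.2), "\\[0, 1\\]")
  expect_error(bin_dwelling_fraction(-0.1), "\\[0, 1\\]")
})

# Build a mapping_result skeleton with prescribed dwelling fractions /
# away counts on a given tree, for summarization fixtures.
fake_mapping <- function(tree, dwell_frac0, away0 = NULL) {
  E <- nrow(tree$edge)
  states <- c("0", "1")
  dwell_frac <- cbind(dwell_frac0, 1 - dwell_frac0)
  colnames(dwell_frac) <- states
  away <- cbind(away0 %||% rep(0, E), rep(0, E))
  colnames(away) <- states
  structure(list(tree = tree, states = states, clade = clade_ids(tree),
                 branch_length = tree$edge.length,
                 dwell = dwell_frac * tree$edge.length,
                 dwell_frac = dwell_frac, away = away,
                 rate = away / pmax(tree$edge.length, 1e-12),
                 pairwise = array(0, c(E, 2, 2)),
                 totals = list()),
            class = "mapping_result")
}

test_that("identical posteriors give point-mass summaries", {
  tr <- simulate_pure_birth_tree(8, 1, seed = 5)
  ts <- as_treeset(rep(list(tr), 10))
  maps <- lapply(1:10, function(k)
    fake_mapping(tr, rep(0.6, nrow(tr$edge))))
  s <- summarize_on_target(tr, ts, maps, state = "0")
  expect_true(all(s$matched_fraction == 1))
  expect_true(all(s$bins[, "bin12"] == 1))  # 0.6 -> bin 12
  expect_lt(max(abs(rowSums(s$bins) - 1)), 1e-10)
  expect_false(any(s$gray))
})

test_that("the 80/20 posterior splits masses across the red and green tones", {
  tr <- simulate_pure_birth_tree(8, 1, seed = 5)
  ts <- as_treeset(rep(list(tr), 10))
  maps <- c(lapply(1:8, function(k) fake_mapping(tr, rep(1.0, nrow(tr$edge)))),
            lapply(1:2, function(k) fake_mapping(tr, rep(0.5, nrow(tr$edge)))))
  s <- summarize_on_target(tr, ts, maps, state = "0")
  expect_equal(unname(s$bins[, "bin20"]), rep(0.8, nrow(tr$edge)))
  expect_equal(unname(s$bins[, "bin10"]), rep(0.2, nrow(tr$edge)))
  expect_equal(unname(rowSums(s$bins)), rep(1, nrow(tr$edge)))
})

test_that("clades absent from every posterior tree are flagged gray", {
  target <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  other <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  ts <- as_treeset(rep(list(other), 4))
  maps <- lapply(1:4, function(k) fake_mapping(other, rep(1, nrow(other$edge))))
  s <- summarize_on_target(target, ts, maps, state = "0")
  ab <- which(s$clade == "A|B")
  expect_true(s$gray[ab])
  expect_equal(s$matched_fraction[ab], 0)
  expect_equal(sum(s$bins[ab, ]), 0)
  # tips always match
  expect_false(s$gray[s$clade == "A"])
  # painted mass + gray remainder accounts for the whole branch
  expect_lt(max(abs(rowSums(s$bins) + (1 - s$matched_fraction) - 1)), 1e-10)
})

test_that("partial matches renormalize only when asked", {
  target <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  other <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  ts <- as_treeset(list(target, other))
  maps <- list(fake_mapping(target, rep(1, nrow(target$edge))),
               fake_mapping(other, rep(1, nrow(other$edge))))
  s <- summarize_on_target(target, ts, maps, state = "0")
  ab <- which(s$clade == "A|B")
  expect_equal(s$matched_fraction[ab], 0.5)
  expect_equal(sum(s$bins[ab, ]), 0.5)
  sr <- summarize_on_target(target, ts, maps, state = "0", renormalize = TRUE)
  expect_equal(sum(sr$bins[ab, ]), 1)
  expect_true(sr$renormalized)
})

test_that("transition counts are binned on a 0-to-max adaptive scale", {
  tr <- simulate_pure_birth_tree(6, 1, seed = 15)
  E <- nrow(tr$edge)
  ts <- as_treeset(list(tr, tr))
  away1 <- seq(0, 4, length.out = E)
  maps <- list(fake_mapping(tr, rep(0.5, E), away0 = away1),
               fake_mapping(tr, rep(0.5, E), away0 = away1))
  s <- summarize_on_target(tr, ts, maps, state = "0",
                           quantity = "transitions")
  expect_equal(s$scale_max, 4)
  expect_equal(sum(s$bins[which.max(away1), "bin20"]), 1)  # max -> top bin
  expect_equal(sum(s$bins[which.min(away1), "bin0"]), 1)   # zero -> bin 0
})

test_that("summaries are invariant to posterior order and match single-tree binning", {
  tr <- simulate_pure_birth_tree(8, 1, seed = 25)
  m <- build_rate_matrix(1, "ER", 2)
  dat <- history_tip_states(simulate_history(tr, m, seed = 26))
  mp <- map_tree(tr, dat, m)
  trees <- as_treeset(rep(list(tr), 3))
  fracs <- list(rep(0.2, nrow(tr$edge)), rep(0.7, nrow(tr$edge)),
                rep(1.0, nrow(tr$edge)))
  maps <- lapply(fracs, function(f) fake_mapping(tr, f))
  s1 <- summarize_on_target(tr, trees, maps, state = "0")
  perm <- c(3, 1, 2)
  s2 <- summarize_on_target(tr, trees, maps[perm], state = "0")
  expect_equal(s1$bins, s2$bins)
  expect_equal(s1$matched_fraction, s2$matched_fraction)

  # single-tree "posterior" = that tree's own mapping binned directly
  s3 <- summarize_on_target(tr, as_treeset(list(tr)), list(mp), state = "0")
  direct <- bin_dwelling_fraction(pmin(pmax(mp$dwell_frac[, 1], 0), 1))
  for (e in seq_along(direct))
    expect_equal(unname(s3$bins[e, direct[e] + 1]), 1)
})

test_that("summary TSVs round-trip and table summarization matches in-memory", {
  tr <- simulate_pure_birth_tree(8, 1, seed = 35)
  m <- build_rate_matrix(1, "ER", 2)
  dat <- history_tip_states(simulate_history(tr, m, seed = 36))
  ts <- as_treeset(list(tr, tr))
  maps <- map_treeset(ts, dat, q_mode = "user", model = m)
  s <- summarize_on_target(tr, ts, maps, state = "0")

  p <- withr::local_tempfile(fileext = ".tsv")
  write_summary_tsv(s, p)
  s2 <- read_summary_tsv(p)
  expect_equal(unname(s2$bins), unname(s$bins), tolerance = 1e-12)
  expect_equal(s2$matched_fraction, s$matched_fraction)
  expect_equal(s2$quantity, s$quantity)

  mt <- withr::local_tempfile(fileext = ".tsv")
  write_mapping_tsv(maps, mt)
  s3 <- summarize_mapping_table(tr, read_mapping_tsv(mt), state = "0")
  expect_equal(unname(s3$bins), unname(s$bins), tolerance = 1e-9)
})
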