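test_that("interolog_predict applies the at-least-one-organism rule", {
  maps <- data.frame(organism = c("yeast", "yeast"),
                     protein = c("r1", "r2"),
                     ortholog = c("y1", "y2"))
  refs <- data.frame(organism = "yeast", idA = "y1", idB = "y2")
  pred <- interolog_predict(maps, refs)
  expect_equal(nrow(pred), 1L)
  expect_equal(c(pred$idA, pred$idB), c("r1", "r2"))
  expect_equal(pred$organisms, "yeast")

  # reference pair stored in the reverse order still transfers (unordered)
  refs_rev <- data.frame(organism = "yeast", idA = "y2", idB = "y1")
  expect_equal(nrow(interolog_predict(maps, refs_rev)), 1L)

  # protein without an ortholog appears in no prediction
  maps2 <- maps[maps$protein != "r1", , drop = FALSE]
  expect_equal(nrow(interolog_predict(maps2, refs)), 0L)

  # support accumulates across organisms
  maps3 <- rbind(maps, data.frame(organism = "human",
                                  protein = c("r1", "r2"),
                                  ortholog = c("h1", "h2")))
  refs3 <- rbind(refs, data.frame(organism = "human", idA = "h1", idB = "h2"))
  pred3 <- interolog_predict(maps3, refs3)
  expect_equal(pred3$n_organisms, 2L)
  expect_equal(pred3$organisms, "human,yeast")
})

test_that("interolog_predict is monotone in the reference sets", {
  set.seed(17)
  orgs <- c("yeast", "fly", "worm")
  maps <- do.call(rbind, lapply(orgs, function(o)
    data.frame(organism = o, protein = sprintf("r%d", 1:10),
               ortholog = sprintf("%s%d", substr(o, 1, 1), sample(6, 10,
                                                                  TRUE)))))
  base_refs <- do.call(rbind, lapply(orgs, function(o) {
    p <- all_vs_all(sprintf("%s%d", substr(o, 1, 1), 1:6))
    p$organism <- o
    p[sample(nrow(p), 5), c("organism", "idA", "idB")]
  }))
  p_small <- interolog_predict(maps, base_refs[1:8, ])
  p_big <- interolog_predict(maps, base_refs)
  k_small <- paste(p_small$idA, p_small$idB)
  k_big <- paste(p_big$idA, p_big$idB)
  expect_true(all(k_small %in% k_big))
})

test_that("winner_takes_all picks the top compartment with documented ties", {
  df <- data.frame(protein = c("p", "p", "q", "t", "t"),
                   compartment = c("nucleus", "cytosol", "mito",
                                   "nucleus", "cytosol"),
                   score = c(9, 3, 4, 5, 5))
  w <- winner_takes_all(df)
  expect_equal(unname(w["p"]), "nucleus")
  expect_equal(unname(w["q"]), "mito")          # single compartment
  expect_equal(unname(w["t"]), "cytosol")       # tie: alphabetical default
  w2 <- winner_takes_all(df, priority = c("nucleus", "cytosol", "mito"))
  expect_equal(unname(w2["t"]), "nucleus")      # tie: explicit priority
  expect_error(winner_takes_all(df[0, ]), "empty")
})

test_that("localization_enrichment computes the exact hypergeometric tail", {
  # closed-form worked example: N=10, K=3, n=4, k=2 -> p = 1/3
  expect_equal(stats::phyper(1, 3, 7, 4, lower.tail = FALSE), 1 / 3,
               tolerance = 1e-12)

  # degenerate universe: everything co-localized -> p = 1
  locs <- setNames(rep("cytosol", 5), sprintf("P%d", 1:5))
  edges <- data.frame(idA = c("P1", "P2"), idB = c("P2", "P3"))
  enr <- localization_enrichment(edges, locs, "cytosol")
  expect_equal(enr$p, 1.0)
  expect_equal(enr$k, enr$n)
  expect_equal(enr$K, enr$N)

  # k = 0 -> upper tail from zero = 1
  locs2 <- setNames(c("cytosol", "cytosol", "nucleus", "nucleus"),
                    sprintf("P%d", 1:4))
  enr2 <- localization_enrichment(data.frame(idA = "P1", idB = "P3"),
                                  locs2, "nucleus")
  expect_equal(enr2$p, 1.0)

  expect_error(localization_enrichment(edges, locs, "vacuole"), "absent")
  expect_error(localization_enrichment(data.frame(idA = "P9", idB = "P1"),
                                       locs, "cytosol"), "without location")
})

test_that("enrichment p matches exhaustive enumeration for small universes", {
  # universes of N = C(P,2) <= 12 pairs: P = 4 gives N = 6
  set.seed(23)
  locs <- setNames(c("a", "a", "b", "b"), sprintf("P%d", 1:4))
  allp <- all_vs_all(names(locs))
  for (n in 2:5) {
    edges <- allp[sample(nrow(allp), n), ]
    enr <- localization_enrichment(edges, locs, "a")
    expect_equal(enr$p,
                 hyper_tail_enum_oracle(enr$k, enr$K, enr$N, enr$n),
                 tolerance = 1e-12)
  }
  # and a 5-protein universe (N = 10 pairs)
  locs5 <- setNames(c("a", "a", "a", "b", "b"), sprintf("Q%d", 1:5))
  allp5 <- all_vs_all(names(locs5))
  for (rep in 1:5) {
    edges <- allp5[sample(nrow(allp5), 4), ]
    enr <- localization_enrichment(edges, locs5, "a")
    expect_equal(enr$p,
                 hyper_tail_enum_oracle(enr$k, enr$K, enr$N, enr$n),
                 tolerance = 1e-12)
  }
})

test_that("coexpression_shift behaves like a one-sided rank-sum test", {
  # maximal separation: exact p = 1 / C(6,3)
  s <- coexpression_shift(c(3, 4, 5), c(0, 1, 2))
  expect_equal(s$U, 9)
  expect_equal(s$p, 0.05)
  expect_equal(s$method, "exact")

  # identical samples: U = nm/2, p ~ 0.5
  s2 <- coexpression_shift(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s2$U, 4.5)
  expect_equal(s2$p, 0.5, tolerance = 0.01)

  # all values tied: tie-corrected p ~ 0.5 (degenerate, no shift)
  s3 <- coexpression_shift(rep(2, 10), rep(2, 10))
  expect_equal(s3$U, 50)
  expect_equal(s3$p, 0.5)

  # exact agrees with the normal approximation at n = m = 30
  set.seed(61)
  x <- rnorm(30, 0.3); y <- rnorm(30)
  big <- coexpression_shift(x, y)
  ref <- stats::wilcox.test(x, y, alternative = "greater", exact = TRUE)
  expect_lt(abs(big$p - ref$p.value), 0.02)
  expect_error(coexpression_shift(numeric(0), 1:3), "non-empty")
})
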