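net_of <- function(...) {
  rows <- list(...)
  grn_network(data.frame(agent = vapply(rows, `[`, "", 1L),
                         label = vapply(rows, `[`, "", 2L),
                         target = vapply(rows, `[`, "", 3L),
                         stringsAsFactors = FALSE))
}

test_that("diff_networks classifies matches, substitutions and inversions", {
  ref <- net_of(c("a", "Activation", "b"))
  ident <- diff_networks(ref, ref)
  expect_equal(ident[c("M", "S", "D", "I")], list(M = 1L, S = 0L, D = 0L,
                                                  I = 0L))
  sub <- diff_networks(ref, net_of(c("a", "Inhibition", "b")))
  expect_equal(sub$S, 1L)
  expect_equal(sub$substitution$ref_label, "Activation")
  expect_equal(sub$substitution$pred_label, "Inhibition")
  expect_equal(sub$M + sub$S + sub$D, sub$N)

  inv <- diff_networks(ref, net_of(c("b", "Activation", "a")))
  expect_equal(inv[c("D", "I", "inversions")],
               list(D = 1L, I = 1L, inversions = 1L))
  inv2 <- diff_networks(ref, net_of(c("b", "Activation", "a")),
                        inversion_policy = "substitution")
  expect_equal(inv2[c("S", "D", "I", "inversions")],
               list(S = 1L, D = 0L, I = 0L, inversions = 1L))
  expect_equal(inv2$M + inv2$S + inv2$D, inv2$N)
})

test_that("injected error counts are recovered exactly", {
  ref <- generate_network(10, 10, seed = 1)
  p <- perturb_network(ref, error_spec(n_delete = 2, n_insert = 3,
                                       n_substitute = 1, seed = 2))
  d <- diff_networks(ref, p$prediction)
  expect_equal(d[c("S", "D", "I")], list(S = 1L, D = 2L, I = 3L))
  expect_equal(score_network(d)$SER, 0.6) # (1 + 2 + 3) / 10
})

test_that("SER, recall, precision arithmetic", {
  # M=1, S=1, D=1, I=1, N=4: SER = 3/4
  ref <- net_of(c("a", "Activation", "b"), c("c", "Binding", "d"),
                c("e", "Regulation", "f"), c("g", "Inhibition", "h"))
  pred <- net_of(c("a", "Activation", "b"),  # match
                 c("c", "Inhibition", "d"),  # substitution
                 c("x", "Binding", "y"))     # insertion; (e,f),(g,h) deleted
  d <- diff_networks(ref, pred)
  expect_equal(d[c("M", "S", "D", "I")], list(M = 1L, S = 1L, D = 2L,
                                              I = 1L))
  sc <- score_network(diff_networks(ref, pred))
  expect_equal(sc$recall, 1 / 4)
  expect_equal(sc$precision, 1 / 3)

  four <- structure(list(M = 1L, S = 1L, D = 1L, I = 1L, N = 4L, P = 3L,
                         inversions = 0L), class = "arc_diff")
  expect_equal(score_network(four)$SER, 0.75)

  expect_equal(score_network(diff_networks(ref, ref))$SER, 0)
  empty <- diff_networks(ref, grn_network())
  expect_equal(score_network(empty)$SER, 1)
  expect_equal(score_network(empty)$recall, 0)
  expect_equal(score_network(empty)$precision, 0)
  expect_error(score_network(diff_networks(grn_network(), grn_network())),
               class = "bteval_undefined_reference")
})

test_that("shape transform collapses labels and multiplicity", {
  multi <- net_of(c("a", "Activation", "b"), c("a", "Binding", "b"))
  sh <- shape_transform(multi)
  expect_equal(nrow(sh$arcs), 1L)
  expect_equal(sh$arcs$label, "Arc")
  expect_equal(nrow(shape_transform(grn_network())$arcs), 0L)
  expect_equal(evaluate_network(multi, multi, mode = "shape")$SER, 0)
  # undirected reading merges directions
  two_way <- net_of(c("a", "Activation", "b"), c("b", "Binding", "a"))
  expect_equal(nrow(shape_transform(two_way)$arcs), 2L)
  expect_equal(nrow(shape_transform(two_way, undirected = TRUE)$arcs), 1L)
})

test_that("effect transform relabels or drops mechanism arcs", {
  expect_equal(effect_transform(net_of(c("a", "Binding", "b")))$arcs$label,
               "Regulation")
  mixed <- effect_transform(net_of(c("a", "Activation", "b"),
                                   c("a", "Binding", "b")))
  expect_equal(mixed$arcs$label, "Activation")
  untouched <- net_of(c("a", "Inhibition", "b"))
  expect_identical(effect_transform(untouched)$arcs, untouched$arcs)
  # Regulation effect arc + mechanism arc: mechanism is redundant
  redundant <- effect_transform(net_of(c("a", "Regulation", "b"),
                                       c("a", "Transcription", "b")))
  expect_equal(redundant$arcs$label, "Regulation")
  expect_equal(nrow(redundant$arcs), 1L)
})

test_that("shape mode never substitutes and never scores above official", {
  for (seed in 1:20) {
    ref <- generate_network(8, 10, seed = seed)
    p <- perturb_network(ref, error_spec(
      n_delete = seed %% 3, n_insert = seed %% 4,
      n_substitute = seed %% 2, n_invert = seed %% 2,
      seed = seed + 100))
    official <- evaluate_network(ref, p$prediction, mode = "official")
    shape <- evaluate_network(ref, p$prediction, mode = "shape")
    expect_equal(shape$diff$S, 0L)
    expect_lte(shape$SER, official$SER)
  }
})

test_that("shape-mode F1 ranking equals shape-mode SER ranking", {
  # holds on families ordered by total error count (see methods vignette:
  # F1 weighs deletions more than insertions, so arbitrary mixes can tie-
  # break differently)
  ref <- generate_network(10, 12, seed = 7)
  scores <- lapply(0:4, function(k) {
    p <- perturb_network(ref, error_spec(n_delete = k, n_insert = k,
                                         seed = k + 1))$prediction
    evaluate_network(ref, p, mode = "shape")
  })
  ser <- vapply(scores, `[[`, 0, "SER")
  f1 <- vapply(scores, `[[`, 0, "f1")
  expect_equal(order(ser), order(-f1))
})

test_that("F-score penalizes a substitution twice, the SER once", {
  ref <- generate_network(10, 10, seed = 3)
  subs <- perturb_network(ref, error_spec(n_substitute = 3,
                                          seed = 4))$prediction
  dels <- perturb_network(ref, error_spec(n_delete = 3,
                                          seed = 4))$prediction
  sc_subs <- evaluate_network(ref, subs)
  sc_dels <- evaluate_network(ref, dels)
  expect_equal(sc_subs$SER, sc_dels$SER) # both 3 errors out of 10
  # same SER, but the substitution run is hit in recall AND precision
  expect_lt(sc_subs$f1, sc_dels$f1)
  expect_equal(sc_subs$recall, 0.7)
  expect_equal(sc_subs$precision, 0.7)
  expect_equal(sc_dels$precision, 1)
})

test_that("networks round-trip through arc lists and GraphML", {
  net <- generate_network(6, 9, seed = 12)
  tsv <- withr::local_tempfile(fileext = ".net")
  write_arc_list(net, tsv)
  expect_identical(read_arc_list(tsv)$arcs, net$arcs)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  expect_identical(read_graphml(gml)$arcs, net$arcs)
  empty <- withr::local_tempfile(fileext = ".net")
  write_arc_list(grn_network(), empty)
  expect_equal(nrow(read_arc_list(empty)$arcs), 0L)
})
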