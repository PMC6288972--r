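ring_genome <- function(weights = c(1L, 1L, 1L)) {
  # types 1 -> 2 -> 3 -> 1 with the given edge signs
  genome(list(gene(1, list(c(3L, weights[3]))),
              gene(2, list(c(1L, weights[1]))),
              gene(3, list(c(2L, weights[2])))))
}

test_that("feedback-loop signs are the product of edge weights", {
  pos <- enumerate_feedback_loops(build_network(ring_genome(c(1L, 1L, 1L))))
  expect_equal(nrow(pos), 1)
  expect_equal(pos$size, 3)
  expect_equal(pos$sign, 1)
  expect_equal(pos$members, "1>2>3")

  neg <- enumerate_feedback_loops(build_network(ring_genome(c(1L, -1L, 1L))))
  expect_equal(neg$sign, -1)

  # self-activation is a size-1 positive loop
  self <- enumerate_feedback_loops(build_network(genome(list(gene(5, list(c(5L, 1L)))))))
  expect_equal(self$size, 1)
  expect_equal(self$sign, 1)
})

test_that("antagonistic parallel edges generate distinct loops", {
  g <- genome(list(gene(1, list(c(2L, 1L))),
                   gene(2, list(c(1L, 1L), c(1L, -1L), c(1L, -1L)))))
  loops <- enumerate_feedback_loops(build_network(g))
  # duplicate same-sign sites collapse; +/+ and +/- cycles remain
  expect_equal(nrow(loops), 2)
  expect_setequal(loops$sign, c(1, -1))
})

test_that("acyclic networks contain no feedback loops", {
  dag <- genome(list(gene(2, list(c(1L, 1L))), gene(3, list(c(2L, -1L))),
                     gene(4, list(c(1L, 1L), c(3L, -1L))), gene(1)))
  loops <- enumerate_feedback_loops(build_network(dag))
  expect_equal(nrow(loops), 0)
})

test_that("the loop census matches brute-force enumeration on random graphs", {
  set.seed(60)
  for (i in 1:100) {
    net <- build_network(random_signed_graph_genome(p_edge = 0.3))
    got <- enumerate_feedback_loops(net)
    ref <- brute_force_loops(net)
    expect_equal(nrow(got), nrow(ref))
    key <- function(df) sort(paste(df$size, df$sign, df$members))
    expect_identical(key(got), key(ref))
  }
})

test_that("the loop cap truncates and flags", {
  # complete signed digraph on 6 nodes has very many simple cycles
  g <- genome(lapply(1:6, function(t)
    gene(t, lapply(setdiff(1:6, t), function(s) c(s, 1L)))))
  res <- enumerate_feedback_loops(build_network(g), max_loops = 10)
  expect_lte(nrow(res), 10)
  expect_true(attr(res, "truncated"))
})

test_that("complexity reports count genes, sites, loops and FFLs", {
  empty <- complexity_report(genome(list()))
  expect_equal(empty$n_genes, 0)
  expect_equal(empty$n_tfbs, 0)
  expect_equal(empty$n_pos_fbl + empty$n_neg_fbl, 0)
  expect_equal(empty$n_ffl, 0)

  # ring 1->2->3->1 plus shortcut 1->3: one FFL, and the shortcut also
  # closes a second (2-gene) feedback loop with the ring edge 3->1
  g <- genome(list(gene(1, list(c(3L, 1L))),
                   gene(2, list(c(1L, 1L))),
                   gene(3, list(c(2L, 1L), c(1L, 1L)))))
  rep_ <- complexity_report(g)
  expect_equal(rep_$n_pos_fbl + rep_$n_neg_fbl, 2)
  expect_equal(rep_$n_ffl, 1)
  expect_equal(as.integer(rep_$loop_size_histogram["3"]), 1)
  expect_equal(as.integer(rep_$loop_size_histogram["2"]), 1)

  # invariant to gene order in the genome
  g_perm <- genome(g$genes[c(3, 1, 2)])
  rep2 <- complexity_report(g_perm)
  expect_equal(rep2$n_pos_fbl, rep_$n_pos_fbl)
  expect_equal(rep2$n_neg_fbl, rep_$n_neg_fbl)
  expect_equal(rep2$n_ffl, rep_$n_ffl)
})

test_that("pruning removes the decoration and nothing the pattern needs", {
  fx <- make_fixture_genome("decorated_core")
  pruned <- prune_genome(fx)
  core <- pruned$genome

  # the decorated extra type-9 copy and its sites are gone
  nine <- Filter(function(g) g$type == 9, core$genes)
  expect_true(all(vapply(nine, function(g) nrow(g$sites), 0L) == 0))
  # the inert sites added to the clock gene are gone
  expect_false(any(vapply(core$genes, function(g)
    any(g$sites[, 1] %in% c(12, 13)), TRUE)))
  # the oscillator ring and switch survive
  expect_true(all(c(1, 2, 3, 4, 6, 5) %in% gene_types(core)))

  # the pruned genome still produces the reference pattern
  sc <- score_genome(core)
  expect_equal(sc$report$n_good, pruned$reference$n_good)

  # idempotence: a second pruning pass removes nothing
  again <- prune_genome(core)
  expect_equal(length(again$removed), 0)
  expect_identical(format_genome(again$genome), format_genome(core))
})

test_that("pruning a genome with an inert duplicate removes that copy", {
  g <- morphogen_reporter_genome()
  g$genes <- c(g$genes, list(gene(11))) # duplicate type with no function
  pruned <- prune_genome(g)
  expect_lt(n_genes(pruned$genome), n_genes(g))
  expect_equal(pruned$reference$n_good,
               score_genome(pruned$genome)$report$n_good)
})
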