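test_that("pairwise protein distance: identity, p, and Poisson correction", {
  expect_equal(as.numeric(pairwise_protein_distance("ACDEFGHIKL", "ACDEFGHIKL")), 0)
  expect_equal(as.numeric(pairwise_protein_distance("ACDEFGHIKL", "ACDEFGHIKV")), 0.1)
  expect_equal(as.numeric(pairwise_protein_distance("ACDEFGHIKL", "ACDEFGHIKV",
                                                    correction = "poisson")),
               -log(0.9), tolerance = 1e-9)
})

test_that("neighbor joining: two- and three-taxon closed forms", {
  dm2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- neighbor_joining(dm2)
  expect_equal(sort(tr2$tip.label), c("A", "B"))
  expect_equal(unname(tr2$edge.length), c(0.2, 0.2))

  dm3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(dm3)
  pend <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(pend[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("NJ reproduces additive matrices exactly (path-length oracle)", {
  for (seed in 1:8) {
    sim <- random_additive_dm(n = 8, seed = seed)
    tr <- neighbor_joining(sim$dm)
    got <- stats::cophenetic(tr)
    got <- got[rownames(sim$dm), colnames(sim$dm)]
    expect_equal(got, sim$dm, tolerance = 1e-8)
    # topology agrees with the generating tree
    expect_equal(ape::dist.topo(ape::unroot(tr), sim$tree), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ matches ape's reference implementation on random additive input", {
  sim <- random_additive_dm(n = 10, seed = 99)
  mine <- neighbor_joining(sim$dm)
  ref <- ape::nj(as.dist(sim$dm))
  expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("NJ is input-order invariant up to isomorphism and rejects bad matrices", {
  sim <- random_additive_dm(n = 7, seed = 3)
  set.seed(11)
  perm <- sample(rownames(sim$dm))
  tr1 <- neighbor_joining(sim$dm)
  tr2 <- neighbor_joining(sim$dm[perm, perm])
  expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)

  bad <- sim$dm; bad[1, 2] <- bad[1, 2] + 1
  expect_error(neighbor_joining(bad), "symmetric")
  nab <- sim$dm; nab[1, 2] <- nab[2, 1] <- NA
  expect_error(neighbor_joining(nab), "NA")
})

test_that("bootstrap supports: determinism, range, and strong-signal recovery", {
  msa <- strong_split_msa()
  expect_error(bootstrap_support(msa, 0), "n_reps")
  t1 <- bootstrap_support(msa, 100, seed = 42)
  t2 <- bootstrap_support(msa, 100, seed = 42)
  expect_identical(attr(t1, "supports"), attr(t2, "supports"))
  s <- attr(t1, "supports")
  expect_true(all(s >= 0 & s <= 100))
  # the AB|CD split (canonical key omits taxon A) is the only internal edge
  expect_named(s, "C|D")
  expect_gte(s[["C|D"]], 95)

  ragged <- c(A = "MKL", B = "MK", C = "MKL")
  expect_error(bootstrap_support(ragged, 10), "ragged")
})

test_that("every-column-identical split gets support 100", {
  msa <- c(A = paste(rep("A", 30), collapse = ""),
           B = paste(rep("A", 30), collapse = ""),
           C = paste(rep("S", 30), collapse = ""),
           D = paste(rep("S", 30), collapse = ""))
  # perturb one residue per sequence so distances are not all-zero ties
  substr(msa["A"], 1, 1) <- "C"; substr(msa["C"], 2, 2) <- "T"
  t1 <- bootstrap_support(msa, 50, seed = 7)
  expect_equal(unname(attr(t1, "supports")[["C|D"]]), 100)
})

test_that("assign_subfamily uses smallest pure clade with nearest-leaf fallback", {
  tr <- ape::read.tree(text = "(((q1:1,(s1:1,s2:1):1):1,(p1:1,p2:1):1):1,(z1:1,x1:4):1);")
  labels <- c(s1 = "STP", s2 = "STP", p1 = "PLT", p2 = "PLT", x1 = "AZT")
  got <- assign_subfamily(tr, labels)
  q1 <- got[got$gene_id == "q1", ]
  expect_equal(q1$subfamily, "STP")
  expect_equal(q1$method, "clade")
  # z1's smallest labelled clade is (z1, x1) -> pure AZT
  z1 <- got[got$gene_id == "z1", ]
  expect_equal(z1$subfamily, "AZT")
  expect_error(assign_subfamily(tr, c(nope = "STP")), "no labelled leaves")
})

test_that("nearest-leaf fallback triggers when every enclosing clade mixes labels", {
  tr <- ape::read.tree(text = "((q1:1,(s1:2,p1:1):1):1,(s2:1,p2:1):1);")
  labels <- c(s1 = "STP", p1 = "PLT", s2 = "STP", p2 = "PLT")
  got <- assign_subfamily(tr, labels)
  q1 <- got[got$gene_id == "q1", ]
  expect_equal(q1$method, "nearest-leaf")
  expect_equal(q1$subfamily, "PLT")  # path to p1 is 3, to s1 is 4
})

test_that("subfamily labels recovered across the packaged family on a consistent tree", {
  t1 <- utils::read.delim(table1_path(), stringsAsFactors = FALSE)
  clades <- vapply(split(t1$gene_id, t1$subfamily), function(g) {
    paste0("(", paste0(g, ":1", collapse = ","), "):1")
  }, "")
  tr <- ape::read.tree(text = paste0("(", paste(clades, collapse = ","), ");"))
  refs <- vapply(split(t1$gene_id, t1$subfamily), `[`, "", 1L)
  labels <- setNames(names(refs), refs)
  got <- assign_subfamily(tr, labels)
  want <- t1$subfamily[match(got$gene_id, t1$gene_id)]
  expect_equal(got$subfamily, want)
  expect_true(all(got$method == "clade"))
})
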