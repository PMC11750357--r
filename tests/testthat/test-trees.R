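test_that("parse_support takes the ultrafast-bootstrap component", {
  expect_equal(parse_support(c("85/92", "100", "", "97.3/100")),
               c(92, 100, NA, 100))
  expect_error(parse_support("abc"), "cannot parse")
})

test_that("rooting uses the outgroup when present, midpoint otherwise", {
  tr <- ape::read.tree(text = "((Wa1:1,Wa2:1)95/95:1,((LhFV:1,V1:1)90/90:1,OG1:3)80/80:1);")
  md <- toy_metadata(tr$tip.label)
  r <- root_for_classification(tr, md)
  og_side <- ape::extract.clade(r, ape::getMRCA(r, c("Wa1", "Wa2")))
  expect_false("OG1" %in% og_side$tip.label)
  tr2 <- ape::read.tree(text = "((Wa1:1,Wa2:1)95/95:1,(LhFV:4,V1:1)90/90:1);")
  r2 <- root_for_classification(tr2, toy_metadata(tr2$tip.label))
  expect_true(ape::is.rooted(r2))
  expect_error(root_for_classification(ape::read.tree(text = "(Wa1:1,Wa2:1);"),
                                       toy_metadata(c("Wa1", "Wa2"))),
               "fewer than 3")
})

test_that("wasp clades require strict support and decompose when it fails", {
  md <- toy_metadata(c("W1", "W2", "LhFV", "V1", "OG1"))
  good <- ape::read.tree(text = "(OG1:3,((W1:1,W2:1)90/95:1,(LhFV:1,V1:1)90/90:1)90/90:1);")
  cl <- wasp_clades(good, md)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$tips, c("W1", "W2"))
  expect_equal(cl[[1]]$support, 95)
  weak <- ape::read.tree(text = "(OG1:3,((W1:1,W2:1)50/60:1,(LhFV:1,V1:1)90/90:1)90/90:1);")
  cl2 <- wasp_clades(weak, md)
  expect_length(cl2, 2L)
  expect_setequal(unlist(lapply(cl2, `[[`, "tips")), c("W1", "W2"))
  # support exactly 80 fails the strict threshold
  at80 <- ape::read.tree(text = "(OG1:3,((W1:1,W2:1)80/80:1,(LhFV:1,V1:1)90/90:1)90/90:1);")
  expect_length(wasp_clades(at80, md), 2L)
})

test_that("nearest viral relative uses the sister majority, walking if needed", {
  md <- toy_metadata(c("W1", "W2", "LhFV1", "LhFV2", "LbFV", "OG1"))
  tr <- ape::read.tree(text = "(OG1:3,(((W1:1,W2:1)95/95:1,(LhFV1:1,LhFV2:1)90/90:1)90/90:1,LbFV:2)90/90:1);")
  r <- root_for_classification(tr, md)
  cl <- wasp_clades(r, md)[[1]]
  nv <- nearest_viral_relative(r, md, cl)
  expect_equal(nv$lineage, "LhFV-like")
  expect_false(nv$walked)
  # wasp-only sister forces a walk toward the root
  tr2 <- ape::read.tree(text = "(OG1:3,(((W1:1,W2:1)50/50:1,W3:1)50/50:1,LbFV:2)90/90:1);")
  md2 <- toy_metadata(tr2$tip.label)
  r2 <- root_for_classification(tr2, md2)
  cl2 <- wasp_clades(r2, md2)
  nv2 <- nearest_viral_relative(r2, md2, cl2[[1]])
  expect_equal(nv2$lineage, "LbFV-like")
  expect_true(nv2$walked)
  expect_error(nearest_viral_relative(
    ape::read.tree(text = "((Wa1:1,Wa2:1)90/90:1,Wa3:1);"),
    toy_metadata(c("Wa1", "Wa2", "Wa3")), 4L), "no virus tips")
})

test_that("classification reproduces the three canonical patterns", {
  # type I: one supported multi-species clade sister to LhFV
  t1 <- ape::read.tree(text = "(OG1:3,(V1:1,(LbFV:1,(LhFV:1,((Wa1:1,Wb1:1)92/96:1,Wc1:1)93/97:1)90/95:1)91/94:1)90/93:1);")
  md1 <- toy_metadata(t1$tip.label)
  expect_equal(classify_gene_tree(t1, md1)$type, "TYPE_I")
  # type II: single wasp sequence adjacent to LbFV
  t2 <- ape::read.tree(text = "(OG1:3,(V1:1,(LhFV:1,(LbFV:1,Wa1:1)92/95:1)90/94:1)90/93:1);")
  expect_equal(classify_gene_tree(t2, toy_metadata(t2$tip.label))$type,
               "TYPE_II")
  # type III: both patterns in one tree
  t3 <- ape::read.tree(text = "(OG1:3,(V1:1,((LhFV:1,(Wa1:1,Wb1:1)93/96:1)91/95:1,(LbFV:1,Wc1:1)92/96:1)90/94:1)90/93:1);")
  c3 <- classify_gene_tree(t3, toy_metadata(t3$tip.label))
  expect_equal(c3$type, "TYPE_III")
  expect_length(c3$clades, 2L)
  # at exactly 80 the multi-tip clade fails and the call degrades
  t4 <- ape::read.tree(text = "(OG1:3,(V1:1,(LbFV:1,(LhFV:1,(Wa1:1,Wb1:1)80/80:1)90/95:1)91/94:1)90/93:1);")
  expect_equal(classify_gene_tree(t4, toy_metadata(t4$tip.label))$type,
               "UNCLASSIFIED")
  # two clades adjacent to the same lineage match none of the three types
  t5 <- ape::read.tree(text = "(OG1:3,((LhFV:1,(Wa1:1,Wb1:1)93/96:1)91/95:1,(V1:1,(Wc1:1,Wd1:1)92/96:1)90/94:1)90/93:1);")
  c5 <- classify_gene_tree(t5, toy_metadata(t5$tip.label))
  expect_equal(c5$type, "UNCLASSIFIED")
  # a nearest relative outside the canonical lineages blocks classification
  t6 <- ape::read.tree(text = "(OG1:3,(LhFV:1,(V1:1,(Wa1:1,Wb1:1)93/96:1)91/95:1)90/93:1);")
  c6 <- classify_gene_tree(t6, toy_metadata(t6$tip.label))
  expect_equal(c6$type, "UNCLASSIFIED")
  expect_match(paste(c6$notes, collapse = " "), "canonical")
})

test_that("classification is invariant to rotation and re-serialization", {
  fx <- mimic_fixture()
  md <- read_tip_metadata(file.path(fx$dir, "tip_metadata.tsv"))
  trees <- fx$ds$manifest$files$trees[c(1, 5, 9, 13, 20)]
  for (tp in trees) {
    tr <- ape::read.tree(file.path(fx$dir, tp))
    base <- classify_gene_tree(tr, md)$type
    rot <- ape::read.tree(text = ape::write.tree(ape::rotate(tr,
      ape::Ntip(tr) + 1L)))
    expect_equal(classify_gene_tree(rot, md)$type, base)
    reser <- ape::read.tree(text = ape::write.tree(tr))
    expect_equal(classify_gene_tree(reser, md)$type, base)
  }
})

test_that("clade finding agrees with a brute-force clade enumerator", {
  # brute force: enumerate every clade (each internal node and tip) on the
  # rooted tree, keep all-wasp ones with support > 80 or singletons, then
  # retain those maximal under set inclusion
  bf_wasp_clades <- function(tree, metadata, min_support = 80) {
    ntip <- ape::Ntip(tree)
    kind <- metadata$kind[match(tree$tip.label, metadata$tip)]
    names(kind) <- tree$tip.label
    all_nodes <- seq_len(ntip + tree$Nnode)
    sets <- lapply(all_nodes, function(n)
      if (n <= ntip) tree$tip.label[n] else
        ape::extract.clade(tree, n)$tip.label)
    ok <- vapply(seq_along(sets), function(i) {
      tips <- sets[[i]]
      if (!all(kind[tips] == "wasp")) return(FALSE)
      if (length(tips) == 1L) return(TRUE)
      sup <- parse_support(tree$node.label[all_nodes[i] - ntip])
      is.finite(sup) && sup > min_support
    }, logical(1))
    keep <- which(ok)
    maximal <- keep[vapply(keep, function(i)
      !any(vapply(keep, function(j)
        j != i && all(sets[[i]] %in% sets[[j]]), logical(1))), logical(1))]
    lapply(sets[maximal], sort)
  }
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n, tip.label = sprintf("T%d", 1:n))
    kinds <- sample(c("wasp", "virus"), n, replace = TRUE, prob = c(0.5, 0.5))
    tr$tip.label <- ifelse(kinds == "wasp", sub("T", "Wa", tr$tip.label),
                           sub("T", "LhFV", tr$tip.label))
    tr$node.label <- sprintf("%d/%d", sample(50:100, tr$Nnode, TRUE),
                             sample(c(50, 70, 81, 95, 100), tr$Nnode, TRUE))
    md <- toy_metadata(tr$tip.label)
    got <- lapply(wasp_clades(tr, md), function(cl) sort(cl$tips))
    want <- bf_wasp_clades(tr, md)
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
  }
})

test_that("mimic gene trees classify exactly as the truth table says", {
  fx <- mimic_fixture()
  truth <- fx$ds$truth_families
  types <- vapply(fx$res$calls, `[[`, character(1), "type")
  expect_equal(unname(types[truth$family]), truth$true_type)
  expect_equal(sum(types == "TYPE_I"), 12L)
  expect_equal(sum(types == "TYPE_II"), 3L)
  expect_equal(sum(types == "TYPE_III"), 5L)
  expect_equal(sum(types == "UNCLASSIFIED"), 5L)
})

test_that("rooting never places a wasp tip above all viruses on mimic trees", {
  fx <- mimic_fixture()
  md <- read_tip_metadata(file.path(fx$dir, "tip_metadata.tsv"))
  for (tp in fx$ds$manifest$files$trees[1:6]) {
    tr <- ape::read.tree(file.path(fx$dir, tp))
    r <- root_for_classification(tr, md)
    root_children <- r$edge[r$edge[, 1] == ape::Ntip(r) + 1L, 2]
    for (ch in root_children) {
      tips <- if (ch <= ape::Ntip(r)) r$tip.label[ch] else
        ape::extract.clade(r, ch)$tip.label
      kinds <- md$kind[match(tips, md$tip)]
      # no root-adjacent subtree is purely wasp
      expect_true(any(kinds == "virus"))
    }
  }
})
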