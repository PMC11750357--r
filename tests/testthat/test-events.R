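.toy_call <- function(family, type, clades = list()) {
  structure(list(family = family, type = type, clades = clades,
                 notes = character(0)), class = "topology_call")
}

.toy_catalog <- function(ids, species, scaffold, family) {
  data.frame(locus_id = ids, species = species, scaffold = scaffold,
             family = family, stringsAsFactors = FALSE)
}

test_that("build_graph creates colocation and homology-clade edges", {
  cat_df <- .toy_catalog(c("A", "B", "C"),
                         c("sp1", "sp1", "sp2"),
                         c("s1", "s1", "s2"),
                         c("famX", "famY", "famY"))
  calls <- list(
    famX = .toy_call("famX", "TYPE_I",
                     list(list(tips = "A", species = "sp1", support = NA,
                               nearest_lineage = "LhFV-like"))),
    famY = .toy_call("famY", "TYPE_I",
                     list(list(tips = c("B", "C"), species = c("sp1", "sp2"),
                               support = 95, nearest_lineage = "LhFV-like"))))
  g <- build_graph(cat_df, calls)
  expect_setequal(paste(g$edges$from, g$edges$to, g$edges$type),
                  c("A B colocation", "B C homology_clade"))
  # unclassified families contribute no homology edges
  calls$famY$type <- "UNCLASSIFIED"
  g2 <- build_graph(cat_df, calls)
  expect_equal(g2$edges$type, "colocation")
  expect_error(build_graph(cat_df, calls["famX"]), "without topology calls")
})

test_that("transitive colocation groups A, B, C into one event", {
  # A-B colocalize in species 1, B'-C in species 2 via the shared family
  cat_df <- .toy_catalog(c("A", "B", "Bp", "C"),
                         c("sp1", "sp1", "sp2", "sp2"),
                         c("s1", "s1", "s2", "s2"),
                         c("famA", "famB", "famB", "famC"))
  calls <- list(
    famA = .toy_call("famA", "UNCLASSIFIED"),
    famB = .toy_call("famB", "TYPE_I",
                     list(list(tips = c("B", "Bp"), species = c("sp1", "sp2"),
                               support = 95, nearest_lineage = "LhFV-like"))),
    famC = .toy_call("famC", "UNCLASSIFIED"))
  res <- group_events(build_graph(cat_df, calls), calls)
  expect_length(res$events, 1L)
  expect_setequal(res$events[[1]]$loci, c("A", "B", "Bp", "C"))
  expect_setequal(res$events[[1]]$species, c("sp1", "sp2"))
})

test_that("an empty graph yields no events and all loci unassigned", {
  cat_df <- .toy_catalog(c("A", "B"), c("sp1", "sp2"), c("s1", "s2"),
                         c("famA", "famA"))
  calls <- list(famA = .toy_call("famA", "UNCLASSIFIED"))
  res <- group_events(build_graph(cat_df, calls), calls)
  expect_length(res$events, 0L)
  expect_setequal(res$unassigned, c("A", "B"))
})

test_that("grouping equals brute-force transitive closure on random graphs", {
  closure_components <- function(ids, from, to) {
    # brute force: repeatedly merge overlapping sets until fixpoint
    comps <- lapply(ids, identity)
    for (k in seq_along(from)) {
      ia <- which(vapply(comps, function(s) from[k] %in% s, logical(1)))
      ib <- which(vapply(comps, function(s) to[k] %in% s, logical(1)))
      if (ia != ib) {
        comps[[ia]] <- union(comps[[ia]], comps[[ib]])
        comps[[ib]] <- NULL
      }
    }
    sort(vapply(comps, function(s) paste(sort(s), collapse = ","),
                character(1)))
  }
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:50, 1)
    ids <- sprintf("L%02d", 1:n)
    m <- sample(0:(2 * n), 1)
    from <- sample(ids, m, replace = TRUE)
    to <- sample(ids, m, replace = TRUE)
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    got <- waspEVE:::.union_find(ids, from, to)
    got_comps <- sort(vapply(split(ids, got), function(s)
      paste(sort(s), collapse = ","), character(1)))
    expect_equal(unname(got_comps), closure_components(ids, from, to))
  }
})

test_that("adding an edge never increases the event count (monotonicity)", {
  set.seed(17)
  n <- 20
  cat_df <- .toy_catalog(sprintf("L%02d", 1:n), rep("sp1", n),
                         sprintf("s%02d", 1:n), rep("famA", n))
  calls <- list(famA = .toy_call("famA", "TYPE_I", list()))
  edges_pool <- t(combn(cat_df$locus_id, 2))
  picks <- edges_pool[sample(nrow(edges_pool), 30), , drop = FALSE]
  prev <- Inf
  for (k in seq(0, 30, by = 5)) {
    g <- build_graph(cat_df, calls)
    if (k > 0)
      g$edges <- data.frame(from = picks[1:k, 1], to = picks[1:k, 2],
                            type = "colocation", provenance = "x",
                            stringsAsFactors = FALSE)
    res <- group_events(g, calls)
    total <- length(res$events) + length(res$unassigned)
    expect_lte(total, prev)
    prev <- total
    # partition property: every locus in exactly one place
    members <- c(unlist(lapply(res$events, `[[`, "loci")), res$unassigned)
    expect_setequal(members, cat_df$locus_id)
    expect_equal(anyDuplicated(members), 0L)
  }
})

test_that("donor lineage is the family majority and conflicts are flagged", {
  cat_df <- .toy_catalog(c("A", "B"), c("sp1", "sp1"), c("s1", "s1"),
                         c("famA", "famB"))
  mk <- function(lin_a, lin_b) list(
    famA = .toy_call("famA", "TYPE_I",
                     list(list(tips = "A", species = "sp1", support = NA,
                               nearest_lineage = lin_a))),
    famB = .toy_call("famB", "TYPE_I",
                     list(list(tips = "B", species = "sp1", support = NA,
                               nearest_lineage = lin_b))))
  calls <- mk("LhFV-like", "LhFV-like")
  res <- group_events(build_graph(cat_df, calls), calls)
  expect_equal(res$events[[1]]$donor_lineage, "LhFV-like")
  expect_false(res$events[[1]]$conflict)
  calls2 <- mk("LhFV-like", "LbFV-like")
  res2 <- group_events(build_graph(cat_df, calls2), calls2)
  expect_true(res2$events[[1]]$conflict)
})

test_that("mimic events recover the planted structure including the overlap", {
  fx <- mimic_fixture()
  evs <- fx$res$events
  expect_length(evs, 2L)
  sizes <- sort(vapply(evs, function(e) length(e$families), integer(1)))
  expect_equal(sizes, c(9L, 18L))
  big <- evs[[which.max(vapply(evs, `[[`, integer(1), "n_loci"))]]
  small <- evs[[which.min(vapply(evs, `[[`, integer(1), "n_loci"))]]
  expect_length(intersect(big$families, small$families), 5L)
  expect_length(big$species, 6L)
  expect_equal(small$species, "Rhoptromeris_sp")
  expect_equal(big$donor_lineage, "LhFV-like")
  expect_equal(small$donor_lineage, "LbFV-like")
  expect_false(big$conflict || small$conflict)
  expect_length(fx$res$unassigned, 3L)
  expect_equal(big$n_loci + small$n_loci, 150L)
})
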