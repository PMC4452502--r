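# Contour extraction, inclusion trees, node classes and nesting depth.

test_that("contour extraction finds closed zero-level curves", {
  rr <- matrix(seq_len(80), 80, 80)
  phi <- 20 - sqrt((rr - 40)^2 + (t(rr) - 40)^2)  # disk interior positive
  cts <- spfseg:::zero_contours(phi)
  expect_length(cts, 1)
  v <- cts[[1]]$vertices
  expect_identical(v[1, ], v[nrow(v), ])          # closed
  expect_lt(abs(cts[[1]]$area - pi * 20^2) / (pi * 20^2), 0.02)
  # no contours when phi never crosses zero
  expect_length(spfseg:::zero_contours(matrix(-2, 30, 30)), 0)
})

test_that("contour maps label contours across snapshot layers", {
  rr <- matrix(seq_len(80), 80, 80)
  d <- sqrt((rr - 40)^2 + (t(rr) - 40)^2)
  snaps <- lapply(c(30, 22, 14, 6), function(r) r - d)
  cm <- build_contour_map(snaps, step = 50)
  expect_s3_class(cm, "contour_map")
  expect_length(cm, 4)                       # one contour per snapshot
  expect_identical(vapply(cm, `[[`, 0, "iteration"), c(50, 100, 150, 200))
  expect_identical(vapply(cm, `[[`, "", "id"), paste0("C", 1:4))
  # a run recorded every `step` iterations keeps those layers plus the
  # final contour
  ph <- disk_phantom(shape = c(64, 64), r = 12)
  fit <- spf_segment(ph$image, config = seg_config(record_step = 2))
  iters <- unique(vapply(contour_map(fit), `[[`, 0, "iteration"))
  expect_identical(sort(iters),
                   sort(unique(c(seq(2, fit$iterations, by = 2),
                                 fit$iterations))))
  expect_length(build_contour_map(list(), 10), 0)
})

test_that("nesting and disjointness produce chains and separate roots", {
  chain <- build_inclusion_tree(list(
    circle_contour(c(0, 0), 30, "outer"),
    circle_contour(c(0, 0), 20, "mid"),
    circle_contour(c(0, 0), 10, "inner")
  ))
  n <- chain$nodes
  expect_identical(n$parent[n$id == "mid"], "outer")
  expect_identical(n$parent[n$id == "inner"], "mid")
  expect_true(is.na(n$parent[n$id == "outer"]))
  expect_identical(n$depth[n$id == "outer"], 3L)
  expect_identical(n$depth[n$id == "inner"], 1L)

  two <- build_inclusion_tree(list(
    circle_contour(c(0, 0), 10, "a"),
    circle_contour(c(0, 40), 10, "b")
  ))
  expect_true(all(is.na(two$nodes$parent)))
})

test_that("partially overlapping contours raise a topology violation", {
  expect_error(build_inclusion_tree(list(
    circle_contour(c(0, 0), 10, "a"),
    circle_contour(c(0, 9), 10, "b")
  )), "topology violation")
})

test_that("the schematic ten-contour map classifies exactly as printed", {
  tree <- build_inclusion_tree(schematic_contours())
  n <- tree$nodes
  cls <- function(k) sort(n$id[n$class == k])
  expect_identical(cls("branching"), c("C1", "C3"))
  expect_identical(cls("base"), c("C2", "C6", "C7"))
  expect_identical(cls("terminal"), sort(c("C5", "C9", "C10")))
  expect_identical(cls("internal"), c("C4", "C8"))  # chain middles
  # every node has exactly one class and child areas are below parents
  expect_false(anyNA(n$class))
  has_p <- !is.na(n$parent)
  expect_true(all(n$area[has_p] <
                    n$area[match(n$parent[has_p], n$id)]))
})

test_that("minimum nesting depth counts the shortest chain inclusively", {
  # branching node over chains of total lengths 2 and 5
  tr <- inclusion_tree(
    ids = c("b", "t1", "x1", "x2", "x3", "t2"),
    parents = c(NA, "b", "b", "x1", "x2", "x3")
  )
  expect_identical(min_nesting_depth(tr, "b"), 2L)
  expect_identical(min_nesting_depth(tr, "t1"), 1L)
  expect_identical(min_nesting_depth(tr, "x1"), 4L)
  expect_error(min_nesting_depth(tr, "nope"), "unknown contour")
})

test_that("nesting depth matches brute-force chain enumeration on random
           forests", {
  # oracle: materialize every descending chain to a leaf, then take the
  # shortest
  brute_depth <- function(parents, ids, id) {
    kids <- function(x) ids[!is.na(parents) & parents == x]
    all_chains <- function(x) {
      k <- kids(x)
      if (length(k) == 0) return(list(x))
      unlist(lapply(k, function(ch) {
        lapply(all_chains(ch), function(p) c(x, p))
      }), recursive = FALSE)
    }
    min(lengths(all_chains(id)))
  }
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:20, 1)
    ids <- paste0("C", seq_len(n))
    # random forest: each node's parent is an earlier node or none
    parents <- c(NA_character_,
                 vapply(2:n, function(i) {
                   if (runif(1) < 0.15) NA_character_ else
                     ids[sample(i - 1L, 1)]
                 }, ""))
    tr <- classify_nodes(inclusion_tree(ids, parents))
    for (id in ids) {
      expect_identical(min_nesting_depth(tr, id),
                       brute_depth(parents, ids, id))
    }
    # classes partition the nodes
    expect_true(all(tr$nodes$class %in%
                      c("branching", "base", "terminal", "internal")))
  }
})

test_that("deeper nesting marks the higher-contrast blob as more salient", {
  # constructed map: one recording front splits around two blobs; the
  # high-contrast blob keeps refining for five recorded steps, the
  # low-contrast one for two before its region is discarded
  shared <- list(circle_contour(c(0, 0), 90, "R", iteration = 1))
  hi <- lapply(1:5, function(k) {
    circle_contour(c(0, -40), 30 - 3 * k, paste0("H", k), iteration = k + 1)
  })
  lo <- lapply(1:2, function(k) {
    circle_contour(c(0, 40), 30 - 3 * k, paste0("L", k), iteration = k + 1)
  })
  tree <- build_inclusion_tree(c(shared, hi, lo))
  n <- tree$nodes
  expect_identical(n$class[n$id == "R"], "branching")
  expect_identical(n$class[n$id == "H1"], "base")
  expect_identical(n$class[n$id == "L1"], "base")
  expect_gt(n$depth[n$id == "H1"], n$depth[n$id == "L1"])
})

test_that("contour maps export to JSON with nesting fields", {
  tree <- build_inclusion_tree(schematic_contours())
  path <- withr::local_tempfile(fileext = ".json")
  export_contour_map(tree, path)
  recs <- jsonlite::read_json(path)
  expect_length(recs, 10)
  byid <- setNames(recs, vapply(recs, `[[`, "", "id"))
  expect_identical(byid$C5$parent, "C4")
  expect_identical(byid$C3$class, "branching")
  expect_identical(byid$C9$depth, 1L)
  expect_length(byid$C1$vertices, 73)  # closed 72-gon
})
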