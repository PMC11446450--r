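hdb_fixture <- function() {
  set.seed(11)
  rbind(cbind(rnorm(40, 0, 1), rnorm(40, 0, 1)),
        cbind(rnorm(40, 6, 1.2), rnorm(40, 1, 1.2)),
        cbind(rnorm(30, 2, 0.8), rnorm(30, 8, 0.8)),
        cbind(runif(15, -4, 10), runif(15, -4, 12)))
}

# Labels produced once by an independent reference implementation of HDBSCAN
# (noise coded -1) on the fixture above, with the core-distance convention
# aligned (reference min_samples counts the point itself, ours does not).
ref_labels <- list(
  "8_5" = "1,1,1,1,1,1,-1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,-1,2,2,2,2,2,2,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-1,-1,2,-1,0,-1,2,1,-1,1,-1,-1,-1,2",
  "10_4" = "1,1,1,1,1,1,-1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,-1,2,2,2,2,2,2,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-1,-1,2,-1,0,-1,2,1,-1,2,-1,-1,-1,2",
  "15_3" = "1,1,1,1,1,1,-1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-1,-1,2,0,0,-1,2,1,-1,2,-1,2,-1,2"
)

partitions_identical <- function(ours, ref) {
  if (!identical(ours == 0L, ref == -1L)) return(FALSE)
  keep <- ours != 0L
  o <- ours[keep]; r <- ref[keep]
  all(tapply(r, o, function(v) length(unique(v)) == 1)) &&
    all(tapply(o, r, function(v) length(unique(v)) == 1))
}

test_that("HDBSCAN reproduces reference clusterings on a mixed fixture", {
  pts <- hdb_fixture()
  for (key in names(ref_labels)) {
    p <- as.integer(strsplit(key, "_")[[1]])
    ours <- hdbscan(pts, min_cluster_size = p[1], min_samples = p[2])
    ref <- as.integer(strsplit(ref_labels[[key]], ",")[[1]])
    expect_true(partitions_identical(ours, ref),
                label = paste("partition match at", key))
  }
})

test_that("HDBSCAN fully recovers well-separated blobs", {
  set.seed(21)
  blobs <- gaussian_blobs(rbind(c(0, 0), c(30, 0), c(0, 30)), 50)
  cl <- hdbscan(blobs$points, min_cluster_size = 10, min_samples = 5)
  expect_equal(ami(cl, blobs$labels), 1)
})

test_that("oversized min_cluster_size yields all-noise", {
  set.seed(22)
  pts <- matrix(rnorm(60), 30)
  cl <- hdbscan(pts, min_cluster_size = 40, min_samples = 5)
  expect_true(all(cl == 0L))
})

test_that("AMI sweep returns the max, retains per-entry values", {
  set.seed(23)
  blobs <- gaussian_blobs(rbind(c(0, 0), c(25, 0), c(0, 25)), 40)
  grid <- tibble::tibble(min_cluster_size = c(5L, 10L, 60L),
                         min_samples = c(5L, 5L, 5L))
  res <- suppressMessages(
    ami_max_hdbscan(blobs$points, blobs$labels, grid = grid)
  )
  sweep_tab <- attr(res, "sweep")
  expect_equal(nrow(sweep_tab), 3)
  expect_equal(as.numeric(res), max(sweep_tab$ami))
  expect_true(all(as.numeric(res) >= sweep_tab$ami))
  expect_gte(as.numeric(res), 0.99)
})

test_that("a one-entry grid equals the AMI of that single clustering", {
  set.seed(24)
  blobs <- gaussian_blobs(rbind(c(0, 0), c(8, 0)), 30)
  grid <- tibble::tibble(min_cluster_size = 10L, min_samples = 5L)
  res <- ami_max_hdbscan(blobs$points, blobs$labels, grid = grid)
  cl <- hdbscan(blobs$points, 10, 5)
  expect_equal(as.numeric(res),
               ami(ifelse(cl == 0, "noise", paste0("c", cl)), blobs$labels))
})

test_that("all-noise grid entries contribute AMI 0 with a note", {
  set.seed(25)
  pts <- matrix(rnorm(80), 40)
  labels <- rep(1:2, each = 20)
  grid <- tibble::tibble(min_cluster_size = 60L, min_samples = 5L)
  expect_message(res <- ami_max_hdbscan(pts, labels, grid = grid), "noise")
  expect_equal(as.numeric(res), 0)
})
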