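test_that("put then get returns a value-identical payload", {
  store <- store_open(tempfile("store_"))
  b <- tiny_batch()
  k <- object_key("aligned", "chr1", 0L)
  store_put(store, k, b)
  expect_equal(as.data.frame(store_get(store, k)), as.data.frame(b))
})

test_that("duplicate keys, missing keys and missing deletes error", {
  store <- store_open(tempfile("store_"))
  k <- object_key("aligned", "chr1", 0L)
  store_put(store, k, tiny_batch())
  expect_error(store_put(store, k, tiny_batch()), "already present")
  expect_error(store_get(store, object_key("aligned", "chr2", 0L)),
               "no such object")
  expect_error(store_delete(store, object_key("x", "y", 1L)), "missing")
})

test_that("retrieved payloads are immutable snapshots", {
  store <- store_open(tempfile("store_"))
  k <- object_key("sorted", "chr1", 0L)
  store_put(store, k, tiny_batch())
  got <- store_get(store, k)
  got$pos[1L] <- 999999L
  again <- store_get(store, k)
  expect_equal(again$pos[1L], 100L)
})

test_that("repeated gets leave store accounting unchanged", {
  store <- store_open(tempfile("store_"))
  store_put(store, object_key("sorted", "chr1", 0L), tiny_batch())
  sz <- store_size(store)
  res <- lapply(1:5, function(i)
    store_get(store, object_key("sorted", "chr1", 0L)))
  for (r in res) expect_equal(as.data.frame(r), as.data.frame(tiny_batch()))
  expect_identical(store_size(store), sz)
})

test_that("delete removes objects from listings", {
  store <- store_open(tempfile("store_"))
  k <- object_key("aligned", "chr1", 0L)
  store_put(store, k, tiny_batch())
  store_delete(store, k)
  expect_length(store_keys(store), 0L)
  expect_length(store_keys(store, "aligned"), 0L)
})

test_that("list_keys follows header chromosome order, then ordinal", {
  store <- store_open(tempfile("store_"))
  hdr <- make_header(c(chr1 = 1000L, chr2 = 1000L))
  store_put(store, object_key("sorted", "chr2", 0L), tiny_batch())
  store_put(store, object_key("sorted", "chr1", 1L), tiny_batch())
  store_put(store, object_key("sorted", "chr1", 0L), tiny_batch())
  keys <- store_keys(store, "sorted", header = hdr)
  expect_equal(vapply(keys, render_key, character(1L)),
               c("sorted/chr1/0", "sorted/chr1/1", "sorted/chr2/0"))
  expect_length(store_keys(store_open(tempfile("empty_"))), 0L)
})

test_that("chunk and delta payload types survive the store round-trip", {
  store <- store_open(tempfile("store_"))
  ch <- sam_chunk(tiny_batch(), "chr1", 0L)
  store_put(store, object_key("aligned", "chr1", 0L), ch)
  back <- store_get(store, object_key("aligned", "chr1", 0L))
  expect_s3_class(back, "sam_chunk")
  expect_equal(as.data.frame(back$batch), as.data.frame(ch$batch))
  expect_equal(back$pos_span, ch$pos_span)
  fd <- flag_delta(c(0L, 1040L, 0L))
  store_put(store, object_key("flagdelta", "chr1", 0L), fd)
  expect_equal(store_get(store, object_key("flagdelta", "chr1", 0L))$flags,
               fd$flags)
  qd <- qual_index_delta(c("III", "JJJ"), c(0L, 2L))
  store_put(store, object_key("qualindex", "chr1", 0L), qd)
  back_qd <- store_get(store, object_key("qualindex", "chr1", 0L))
  expect_equal(back_qd$index, c(0L, 2L))
  expect_equal(back_qd$qual, c("III", "JJJ"))
})

test_that("capacity bound is enforced as a hard error", {
  store <- store_open(tempfile("store_"), capacity_bytes = 10)
  expect_error(store_put(store, object_key("a", "chr1", 0L), tiny_batch()),
               "capacity")
})

test_that("objects sealed by one process are readable by another", {
  dir <- tempfile("store2p_")
  store <- store_open(dir)
  sim <- sim_small(n_fragments = 50L, dup_groups = 5L)
  # writer and reader run as two separate concurrent worker processes
  cl <- parallel::makeCluster(2L)
  on.exit(parallel::stopCluster(cl), add = TRUE)
  parallel::clusterExport(cl, c("dir", "sim"), envir = environment())
  parallel::clusterEvalQ(cl, library(colsam))
  got <- parallel::clusterApply(cl, 1:2, function(role) {
    st <- colsam::store_open(dir)
    if (role == 1L) {
      colsam::store_put(st, colsam::object_key("aligned", "chr1", 0L),
                        sim$batch)
      "written"
    } else {
      # wait until the writer has sealed the object
      k <- colsam::object_key("aligned", "chr1", 0L)
      for (i in 1:200) {
        if (colsam::store_has(st, k)) break
        Sys.sleep(0.05)
      }
      colsam::store_get(st, k)
    }
  })
  expect_equal(got[[1L]], "written")
  expect_equal(as.data.frame(got[[2L]]), as.data.frame(sim$batch))
})

test_that("dropping a namespace removes exactly that generation", {
  store <- store_open(tempfile("store_"))
  store_put(store, object_key("aligned", "chr1", 0L), tiny_batch())
  store_put(store, object_key("sorted", "chr1", 0L), tiny_batch())
  n <- store_drop_namespace(store, "aligned")
  expect_equal(n, 1L)
  expect_length(store_keys(store, "aligned"), 0L)
  expect_length(store_keys(store, "sorted"), 1L)
})
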