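test_that("double-stain ratio arithmetic", {
  obj <- make_measured_objects(list(cy3 = c(1.0, 1.0, 0.5, 0),
                                    cy5 = c(0.2, 0.4, 0.5, 0)))
  r <- double_stain_ratio(obj)
  expect_equal(r, c(0.2, 0.4, 1.0, 0))
})

test_that("ratios compare stain, not background offsets", {
  obj <- make_measured_objects(list(cy3 = c(0.52), cy5 = c(0.12)),
                               bg_mean = list(cy3 = c(0.02), cy5 = c(0.10)))
  # after background subtraction: cy3 0.5, cy5 0.02 -> ratio 0.04
  expect_equal(double_stain_ratio(obj), 0.04)
})

test_that("bases are called from the dominant coded channel", {
  obj <- make_measured_objects(list(cy3 = c(0.05, 0.50, 0.01, 0.01),
                                    cy5 = c(0.50, 0.05, 0.01, 0.30)))
  calls <- call_bases(obj, min_signal = 0.05)
  expect_equal(calls$called_base, c("A", "G", "no_call", "A"))
  expect_equal(calls$status, c("accepted", "accepted", "no_call", "accepted"))
  expect_equal(calls$dominant_channel, c("cy5", "cy3", "none", "cy5"))
  # blank-base calling, when enabled, turns absent signal into the blank base
  cb <- call_bases(obj, base_coding_map(call_blank = TRUE), min_signal = 0.05)
  expect_equal(cb$called_base[3], "C")
  expect_equal(cb$status[3], "accepted")
})

test_that("the double-stain boundary keeps 0.3 and rejects just above", {
  obj <- make_measured_objects(list(cy3 = c(1.0, 1.0), cy5 = c(0.3, 0.3 + 1e-9)))
  calls <- call_bases(obj, min_signal = 0.01)
  expect_equal(calls$status, c("accepted", "rejected_double_stain"))
  expect_equal(calls$called_base[1], "G")
  expect_equal(calls$called_base[2], "no_call")
})

test_that("calls are invariant under intensity rescaling", {
  obj1 <- make_measured_objects(list(cy3 = c(0.4, 0.2), cy5 = c(0.1, 0.18)),
                                bg_mean = list(cy3 = c(0.02, 0.02),
                                               cy5 = c(0.02, 0.02)))
  sc <- 0.5
  obj2 <- make_measured_objects(list(cy3 = sc * c(0.4, 0.2),
                                     cy5 = sc * c(0.1, 0.18)),
                                bg_mean = list(cy3 = sc * c(0.02, 0.02),
                                               cy5 = sc * c(0.02, 0.02)))
  c1 <- call_bases(obj1, min_signal = 0.01)
  c2 <- call_bases(obj2, min_signal = 0.01 * sc)
  expect_equal(c1$called_base, c2$called_base)
  expect_equal(c1$double_stain_ratio, c2$double_stain_ratio)
})

test_that("anchor gating rejects anchor-negative objects", {
  obj <- make_measured_objects(list(cy3 = c(0.4, 0.4, 0.4),
                                    anchor = c(0.0, 0.30, 0.5)))
  g <- anchor_gate(obj, anchor_min_intensity = 0.1)
  expect_equal(g$kept$object_id, c(2, 3))
  expect_equal(g$rejected$status, "rejected_no_anchor")
  all_in <- anchor_gate(obj, anchor_min_intensity = 0)
  expect_equal(nrow(all_in$kept), 3)
  no_anchor <- make_measured_objects(list(cy3 = c(0.4)))
  expect_warning(g2 <- anchor_gate(no_anchor), "skipped")
  expect_equal(nrow(g2$kept), 1)
})

test_that("rendered artifacts without anchor stain are fully gated out", {
  cfg <- scene_config(image_height_px = 512, image_width_px = 512,
                      spot_density = 80, artifact_density = 40,
                      peak_snr = 8, mutant_fraction = 0.5,
                      include_anchor = TRUE, seed = 55)
  scene <- render_scene(cfg)
  set <- preprocess_stacks(scene$stacks)
  objs <- detect_scene(set)
  m <- match_to_truth(objs, scene$truth, 2)
  g <- anchor_gate(objs)
  art <- m$matches[m$matches$class == "artifact", ]
  rcp_ids <- m$matches$object_id[m$matches$class == "rcp"]
  expect_gt(nrow(art), 5)
  # an artifact lying on top of a true RCP inherits its anchor stain;
  # isolated artifacts must be rejected without exception
  rcp_tr <- scene$truth[scene$truth$class == "rcp", ]
  isolated <- vapply(art$truth_id, function(tid) {
    tr <- scene$truth[scene$truth$object_id == tid, ]
    min(sqrt((rcp_tr$row - tr$row)^2 + (rcp_tr$col - tr$col)^2)) > 5
  }, logical(1))
  expect_true(all(art$object_id[isolated] %in% g$rejected$object_id))
  expect_gte(mean(art$object_id %in% g$rejected$object_id), 0.9)
  expect_gte(mean(rcp_ids %in% g$kept$object_id), 0.9)
})

test_that("tallies preserve totals and count by base and status", {
  calls <- data.frame(
    object_id = 1:6,
    called_base = c("A", "G", "G", "no_call", "no_call", "A"),
    status = c("accepted", "accepted", "accepted", "rejected_double_stain",
               "no_call", "rejected_no_anchor"),
    dominant_channel = "cy5", double_stain_ratio = 0)
  # an anchor-rejected row keeps its base out of the accepted tally
  t <- tally_calls(calls)
  expect_equal(unname(t$base_counts[c("A", "G")]), c(1, 2))
  expect_equal(sum(t$status_counts), t$total)
  expect_equal(t$total, 6)
  # the published 9 mutant / 1552 wild-type contract
  big <- data.frame(object_id = seq_len(1561),
                    called_base = c(rep("A", 9), rep("G", 1552)),
                    status = "accepted", dominant_channel = "cy5",
                    double_stain_ratio = 0)
  tb <- tally_calls(big)
  expect_equal(unname(tb$base_counts[c("A", "G")]), c(9, 1552))
  empty <- tally_calls(big[0, ])
  expect_true(all(empty$base_counts == 0))
  expect_equal(empty$total, 0)
})

test_that("call conservation holds on a full synthetic scene", {
  fx <- std_scene()
  objs <- detect_scene(fx$set)
  mo <- objs  # already measured by detect_scene
  calls <- call_bases(mo)
  t <- tally_calls(calls)
  expect_equal(sum(t$status_counts), nrow(mo))
  expect_equal(t$total, nrow(mo))
})

test_that("coding map validation", {
  expect_error(base_coding_map(channels = c(cy5 = "A", cy3 = "A")),
               "at most one channel")
  expect_error(base_coding_map(channels = c(anchor = "A")), "anchor")
  obj <- make_measured_objects(list(txred = 0.5))
  expect_error(call_bases(obj, base_coding_map(channels = c(cy5 = "A"))),
               "no coded channels")
})
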