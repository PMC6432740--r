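test_that("the face-expression design is fully balanced", {
  set.seed(51)
  d <- design_exp1a(1)
  probes <- d[d$probed, ]
  expect_equal(nrow(probes), 3000)           # 5 blocks x 600 trials
  expect_equal(sort(unique(probes$set_size)), 1:5)
  # rows per trial equal the set size; exactly one probed item per trial
  key <- paste(d$block, d$trial)
  expect_true(all(tapply(d$probed, key, sum) == 1))
  expect_true(all(tapply(rep(1, nrow(d)), key, sum) == d$set_size[!duplicated(key)]))
  lv <- expression_intensity_levels()
  expect_equal(sort(unique(probes$target)), lv)
  expect_equal(min(lv), 10); expect_equal(max(lv), 91); expect_length(lv, 10)
  for (b in c(1, 4)) {
    blk <- probes[probes$block == b, ]
    expect_equal(as.vector(table(blk$emotion)), rep(120L, 5)) # 60 ids x 2
    expect_true(all(table(blk$identity) == 10))            # probed 10x
    # per identity-emotion: one low and one high intensity
    lowhigh <- tapply(blk$target < 50, paste(blk$identity, blk$emotion),
                      function(x) sum(x) == 1 && length(x) == 2)
    expect_true(all(lowhigh))
    expect_true(all(table(blk$target) == 60))              # levels balanced
  }
  # optional final set-size-1 block: each identity-emotion pair once
  d6 <- design_exp1a(1, include_final_block = TRUE)
  final <- d6[d6$block == 6, ]
  expect_equal(nrow(final), 300)
  expect_true(all(final$probed) && all(final$set_size == 1))
  expect_equal(nrow(unique(final[c("identity", "emotion")])), 300)
})

test_that("the grating design covers orientation space uniformly", {
  set.seed(52)
  d <- design_exp1b(1)
  expect_equal(sort(unique(d$set_size)), c(1, 3, 5))
  expect_true(all(d$item_kind == "grating"))
  probes <- d[d$probed, ]
  expect_equal(as.vector(table(probes$set_size)), rep(600L, 3))
  cnt <- tabulate(findInterval(d$target, seq(0, 180, by = 10)), 18)
  expect_gt(chisq.test(cnt)$p.value, 0.001)
})

test_that("mixed arrays hold one face plus one or three gratings", {
  set.seed(53)
  d <- design_exp1c(1, n_trials_per_composition = 200)
  key <- paste(d$trial)
  comp <- tapply(d$item_kind == "grating", key, sum)
  expect_true(all(comp %in% c(1, 3)))
  expect_true(all(tapply(d$item_kind == "face", key, sum) == 1))
  probes <- d[d$probed, ]
  expect_true(all(c("face", "grating") %in% probes$item_kind))
  faces <- d[d$item_kind == "face", ]
  expect_gt(chisq.test(table(faces$emotion))$p.value, 0.001)
})

test_that("responses are generated only for probed items and stay in range", {
  set.seed(54)
  d <- generate_responses(design_exp1c(1, n_trials_per_composition = 100))
  expect_true(all(!is.na(d$response[d$probed])))
  expect_true(all(is.na(d$response[!d$probed])))
  f <- d$probed & d$item_kind == "face"
  g <- d$probed & d$item_kind == "grating"
  expect_true(all(d$response[f] >= 0 & d$response[f] <= 100))
  expect_true(all(d$response[g] >= 0 & d$response[g] < 180))
  expect_error(generate_responses(d), "already contains")
})

test_that("emotion-ordered gains yield the opposite dispersion ordering", {
  set.seed(55)
  trials <- generate_responses(design_exp1a(2)) # 1200 trials per emotion
  probes <- trials[trials$probed, ]
  s <- summarize_trials(probes, "emotion", intensity_space())
  gains <- generating_model()$gain_emotions
  expect_equal(s$emotion[which.max(s$sd)], "sad")    # lowest gain
  expect_true(s$emotion[which.min(s$sd)] %in% c("happy", "disgusted"))
  expect_lt(s$sd[s$emotion == "happy"], s$sd[s$emotion == "fearful"])
  # rank agreement between gain and precision (qualitative ordering)
  expect_lte(cor(s$sd, gains[s$emotion], method = "spearman"), -0.8)
})

test_that("the dual-resource rule produces the face-grating asymmetry", {
  mod <- generating_model() # face_orientation_load = 1
  # grating probed alone vs with one face: effective orientation load 1 vs 2
  base <- tibble::tibble(participant = 1L, experiment = "1C", block = 1L,
                         trial = 1:800, set_size = 1L, item_kind = "grating",
                         emotion = NA_character_, identity = NA_integer_,
                         target = runif(800, 0, 180), response = NA_real_,
                         probed = TRUE)
  withface <- dplyr::bind_rows(base, dplyr::mutate(base, item_kind = "face",
      emotion = "angry", identity = 1L, target = 50, probed = FALSE))
  withface$set_size <- 2L
  set.seed(56)
  r0 <- generate_responses(base, mod)
  set.seed(57)
  r1 <- generate_responses(withface, mod)
  sp <- orientation_space()
  sd0 <- error_dispersion(signed_error(sp, base$target, r0$response[r0$probed]), sp)
  sd1 <- error_dispersion(signed_error(sp, base$target, r1$response[r1$probed]), sp)
  expect_gt(sd1, sd0)
  # face probed with 1 vs 3 gratings: expression load is 1 in both
  face1 <- tibble::tibble(participant = 1L, experiment = "1C", block = 1L,
                          trial = 1:1000, set_size = 2L, item_kind = "face",
                          emotion = "happy", identity = 1L, target = 46,
                          response = NA_real_, probed = TRUE)
  grat <- dplyr::mutate(face1, item_kind = "grating", emotion = NA_character_,
                        identity = NA_integer_,
                        target = runif(1000, 0, 180), probed = FALSE)
  arr1 <- dplyr::bind_rows(face1, grat)
  arr3 <- dplyr::bind_rows(dplyr::mutate(face1, set_size = 4L),
                           dplyr::mutate(grat, set_size = 4L),
                           dplyr::mutate(grat, set_size = 4L,
                                         target = runif(1000, 0, 180)),
                           dplyr::mutate(grat, set_size = 4L,
                                         target = runif(1000, 0, 180)))
  set.seed(58)
  q1 <- generate_responses(arr1, mod)
  set.seed(58)
  q3 <- generate_responses(arr3, mod)
  e1 <- q1$response[q1$probed] - 46
  e3 <- q3$response[q3$probed] - 46
  # same expression load, same seed: identical error distributions
  expect_equal(e1, e3)
})

test_that("grating-only arrays are unaffected by the face load weight", {
  d <- design_exp1b(1)[1:9, ]
  m1 <- generating_model(face_orientation_load = 0)
  m2 <- generating_model(face_orientation_load = 1)
  set.seed(59); a <- generate_responses(d, m1)
  set.seed(59); b <- generate_responses(d, m2)
  expect_equal(a$response, b$response)
})
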