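# A deterministic three-episode dataset: episode 1 chunks task-set A by
# cycling its three pairs with rewards; episode 2 (task-set B) has no correct
# response; episode 3 reuses task-set A, so its first correct trial retrieves
# a chunked cluster.
chunking_dataset <- function() {
  tsA <- c(1L, 2L, 3L)   # stimulus i -> action i
  tsB <- c(2L, 3L, 4L)
  ep1_s <- rep(1:3, 6)
  ep1_a <- tsA[ep1_s]
  ep2_s <- rep(1:3, 2)
  ep2_a <- tsB[c(2, 3, 1)][ep2_s]     # always wrong for task-set B
  ep3_s <- c(1L, 2L, 3L)
  ep3_a <- c(tsA[1], tsA[2], tsA[3])
  make_dataset(
    episode = rep(1:3, c(18, 6, 3)),
    stimulus = c(ep1_s, ep2_s, ep3_s),
    action = c(ep1_a, ep2_a, ep3_a),
    correct_action = c(tsA[ep1_s], tsB[ep2_s], tsA[ep3_s]))
}

test_that("retrieval trials are labeled by rewarded closure membership", {
  pars <- model_params(0.4, 7, 0, qp = 0.4, j_inc = 0.7)
  ds <- chunking_dataset()
  labs <- label_retrieval_trials(ds, pars)
  # episode 2 has no correct response: no label; episode 1's first correct
  # happens before any chunking: independent; episode 3 retrieves.
  expect_identical(sort(unique(labs$episode)), c(1L, 3L))
  expect_identical(labs$label[labs$episode == 1], "independent")
  expect_identical(labs$label[labs$episode == 3], "chunked")
  expect_true(all(labs$kind == "retrieval"))
  # deterministic: relabeling is bit-identical
  expect_identical(labs, label_retrieval_trials(ds, pars))

  # an unchunked scorer labels everything independent
  labs0 <- label_retrieval_trials(ds, model_params(0.4, 7, 0, qp = 0,
                                                   j_inc = 0.7))
  expect_true(all(labs0$label == "independent"))
})

test_that("misleading-reward trials are labeled and noise-free sessions give none", {
  pars <- model_params(0.35, 7, 0.05, qp = 0.17, j_inc = 0.7)
  set.seed(61)
  sim <- quick_subject(pars, session_config(n_episodes = 10))
  labs <- label_misleading_trials(sim$dataset, pars)
  if (nrow(labs)) {
    expect_true(all(labs$kind == "misleading"))
    # every labeled trial follows an incorrect-but-rewarded trial
    expect_true(all(sim$dataset$reward[labs$trial - 1] == 1))
    expect_true(all(sim$dataset$correct[labs$trial - 1] == 0))
    expect_true(all(sim$dataset$stimulus[labs$trial] !=
                      sim$dataset$stimulus[labs$trial - 1]))
  }
  # no noise, no misleading rewards, no labels
  clean <- quick_subject(pars, session_config(n_episodes = 4,
                                              noise_fraction = 0))
  expect_identical(nrow(label_misleading_trials(clean$dataset, pars)), 0L)
})

test_that("chunked labels separate performance only for the inference scorer", {
  pars <- model_params(0.35, 7, 0.05, qp = 0.17, j_inc = 0.7)
  set.seed(62)
  lr <- list(); lm <- list()
  for (i in 1:6) {
    sim <- quick_subject(pars, subject = paste0("s", i))
    tr <- teacher_forced_run(pars, sim$dataset)
    tr0 <- teacher_forced_run(pars, sim$dataset, with_inference = FALSE)
    lr[[i]] <- label_retrieval_trials(sim$dataset, pars, trace = tr,
                                      scorer_trace = tr0)
    lr[[i]]$full_p <- tr$p_correct[lr[[i]]$trial]
    lm[[i]] <- label_misleading_trials(sim$dataset, pars, trace = tr,
                                       scorer_trace = tr0)
    lm[[i]]$full_p <- tr$p_correct[lm[[i]]$trial]
  }
  lr <- do.call(rbind, lr); lm <- do.call(rbind, lm)
  gap <- function(d, col) mean(d[[col]][d$label == "chunked"]) -
    mean(d[[col]][d$label == "independent"])
  expect_gt(gap(lr, "full_p"), 0)     # retrieval helps
  expect_lt(gap(lm, "full_p"), 0)     # maladaptive retrieval hurts
  # the AN-only scorer sees little of the retrieval effect (the
  # relative-magnitude check on both label kinds runs on the larger
  # cohort of the acceptance suite)
  expect_lt(abs(gap(lr, "model_p_correct")), abs(gap(lr, "full_p")))
})

test_that("aligned curves have the expected shape around task events", {
  # all-correct deterministic data: constant curve at 1
  ds <- make_dataset(rep(1:2, each = 10), rep(1:2, 10),
                     rep(c(1L, 2L), 10), rep(c(1L, 2L), 10))
  cur <- aligned_performance(ds, "episode_switch", offsets = -3:3)
  expect_true(all(cur$mean == 1))
  expect_s3_class(cur, "aligned_curve")

  # simulated agent: high before a switch, at/below chance right after
  set.seed(63)
  sims <- lapply(1:5, function(i)
    quick_subject(model_params(0.4, 7, 0, qp = 0.17, j_inc = 0.7)))
  curves <- aligned_performance(lapply(sims, `[[`, "dataset"),
                                "episode_switch", offsets = -3:2)
  pre <- curves$mean[curves$offset == -1]
  post <- curves$mean[curves$offset == 0]
  expect_gt(pre, 0.7)
  expect_lt(post, 0.4)

  # first-correct alignment with the idealized network: retrieval causes a
  # one-trial jump, absent in the control; the previous task-set's still-
  # potentiated weights keep the post-jump level below the late asymptote
  pool <- fixed_pool()
  set.seed(64)
  mk <- function(with_inf) lapply(1:6, function(i) {
    plan <- generate_session(session_config(), pool = pool)
    simulate_session(model_params(0.4, 7, 0, j_inc = 1), plan,
                     with_inference = with_inf,
                     tn0 = if (with_inf) tn_idealized(pool, 3, 4) else NULL,
                     freeze_tn = TRUE)
  })
  jump <- function(sims) {
    fc <- aligned_performance(lapply(sims, `[[`, "dataset"), "first_correct",
                              offsets = 0:1,
                              performance = lapply(sims, function(s)
                                s$trace$p_correct))
    c(at1 = fc$mean[fc$offset == 1],
      rise = fc$mean[fc$offset == 1] - fc$mean[fc$offset == 0])
  }
  with_inf <- jump(mk(TRUE))
  without <- jump(mk(FALSE))
  expect_gt(with_inf["rise"], 0.25)
  expect_lt(without["rise"], 0.15)
  expect_gt(with_inf["at1"] - without["at1"], 0.2)

  expect_error(aligned_performance(ds, "misleading_late"), "no alignment")
})

test_that("newly seen stimuli are scored from the first correct response", {
  # single episode, first correct on the very first trial: the two later
  # stimuli are both eligible, in order of appearance
  ds <- make_dataset(rep(1L, 6), c(1L, 2L, 3L, 2L, 3L, 1L),
                     c(1L, 2L, 4L, 2L, 3L, 1L),
                     c(1L, 2L, 3L)[c(1L, 2L, 3L, 2L, 3L, 1L)])
  out <- newly_seen_performance(ds)
  expect_identical(out$n_second, 1L)
  expect_identical(out$n_third, 1L)
  expect_identical(out$second, 1)   # stimulus 2 answered correctly
  expect_identical(out$third, 0)    # stimulus 3 answered wrong at first sight

  # episodes where every stimulus precedes the first correct are excluded
  ds2 <- make_dataset(rep(1L, 4), c(1L, 2L, 3L, 1L),
                      c(2L, 3L, 4L, 1L), c(1L, 2L, 3L, 1L))
  out2 <- newly_seen_performance(ds2)
  expect_identical(out2$n_second, 0L)

  # idealized retrieval far outperforms gradual learning on newly seen
  # stimuli; it is not at ceiling because the previous task-set's weights
  # for a stimulus unseen since the switch are still potentiated and
  # compete with the retrieved association (the levels land near the
  # 0.5-0.65 range the task's winner-take-all arithmetic dictates)
  pool <- fixed_pool()
  set.seed(65)
  ideal <- lapply(1:15, function(i) {
    plan <- generate_session(session_config(), pool = pool)
    simulate_session(model_params(0.4, 7, 0, j_inc = 1), plan,
                     tn0 = tn_idealized(pool, 3, 4),
                     freeze_tn = TRUE)$dataset
  })
  plain <- lapply(1:15, function(i)
    quick_subject(model_params(0.4, 7, 0), with_inference = FALSE)$dataset)
  hi <- newly_seen_performance(ideal)
  lo <- newly_seen_performance(plain)
  expect_gt(hi$second, 0.25)
  expect_gt(hi$third, 0.25)
  expect_gt(hi$second, lo$second + 0.15)
  expect_gt(hi$third, lo$third + 0.15)
})

test_that("within-episode positions of the two label classes can be compared", {
  pars <- model_params(0.35, 7, 0.05, qp = 0.17, j_inc = 0.7)
  set.seed(66)
  labs <- do.call(rbind, lapply(1:4, function(i) {
    sim <- quick_subject(pars, subject = paste0("s", i))
    label_retrieval_trials(sim$dataset, pars)
  }))
  pos_c <- labs$position[labs$label == "chunked"]
  pos_i <- labs$position[labs$label == "independent"]
  expect_gt(length(pos_c), 5)
  expect_gt(length(pos_i), 5)
  ks <- suppressWarnings(stats::ks.test(pos_c, pos_i))
  expect_true(is.finite(ks$statistic) && ks$p.value >= 0 && ks$p.value <= 1)
})
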