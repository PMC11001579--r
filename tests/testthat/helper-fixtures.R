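# shared fixtures, all generated in code

# hand-built eight-press session on a two-block schedule
tiny_session <- function() {
  sched <- vi_schedule(data.frame(box1_vi = c(10, 20),
                                  box2_vi = c(20, 10),
                                  n_rewards = c(3, 3)))
  presses <- data.frame(
    time_s = c(4, 9, 13, 20, 26, 35, 41, 50),
    box = c(1, 1, 1, 2, 2, 2, 1, 1),
    rewarded = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    block_index = c(1, 1, 1, 1, 2, 2, 2, 2))
  behavioral_session(presses, sched)
}

# unbalanced schedule built from alternating reversal blocks
reversal_schedule <- function(v1, v2, n_rewards = 66, n_blocks = 2) {
  ix <- seq_len(n_blocks)
  vi_schedule(data.frame(
    box1_vi = ifelse(ix %% 2 == 1, v1, v2),
    box2_vi = ifelse(ix %% 2 == 1, v2, v1),
    n_rewards = n_rewards))
}

# small synthetic bundle shared by preprocessing/CCA tests (cached per
# test run; ~20 units keeps it fast)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(list(
        spec = encoding_spec(n_units = 20),
        schedule = vi_schedule(data.frame(box1_vi = 20, box2_vi = 20,
                                          n_rewards = 40))),
        seed = 404L)
    }
    cache
  }
})
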