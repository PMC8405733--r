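# Desk-scale end-to-end fits shared by the training-behaviour tests.
# Conditions: easy (high-contrast) synthetic split, 200/50/50 scenes at
# 96x96 with 0-3 fish; stride-4 small backbone; Adam 1e-3 for 10 epochs.
# Computed once per test run on first use.

.fit_cache <- new.env(parent = emptyenv())

desk_train_config <- function(method, seed) {
  train_config(method = method, learning_rates = 1e-3, max_epochs = 10,
               patience = 10, seed = seed, backbone = "small4",
               student_epochs = 8, student_lr = 1e-3)
}

desk_fits <- function(seeds = 1:3) {
  key <- paste0("fits_", paste(seeds, collapse = "_"))
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  sp <- easy_scene_spec()
  out <- list()
  for (seed in seeds) {
    man <- generate_split(sp, 200, 50, 50, seed = seed)
    teacher <- train(man, desk_train_config("a_lcfcn", seed))
    plain <- train(man, desk_train_config("lcfcn", seed))
    student <- alcfcn:::distill_fit(teacher, man, desk_train_config("a_lcfcn_pm", seed))
    out[[as.character(seed)]] <- list(
      man = man,
      a_lcfcn = evaluate(teacher, man, "test"),
      lcfcn = evaluate(plain, man, "test"),
      student = evaluate(student, man, "test")
    )
  }
  .fit_cache[[key]] <- out
  out
}
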