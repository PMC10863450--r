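test_that("a minimal document loads into a 1x1x1 study tree", {
  doc <- '{
    "schema_version": 1,
    "study_code": "MINI",
    "title": "Minimal",
    "interventions": [{
      "id": "arm", "name": "Arm",
      "modules": [{
        "id": "m1", "title": "Module 1",
        "items": [{"id": "q1", "item_type": "slider", "prompt": "Mood?",
                   "variable": "mood"}],
        "opening_rules": [{"rule": "relative_to_intervention_start",
                           "offset_minutes": 0}]
      }]
    }]
  }'
  s <- load_study(doc)
  expect_s3_class(s, "study_definition")
  expect_length(s$interventions, 1)
  expect_length(s$interventions[[1]]$modules, 1)
  expect_length(s$interventions[[1]]$modules[[1]]$items, 1)
  expect_equal(s$interventions[[1]]$assignment_policy, "auto_assign")
  expect_identical(load_study(save_study(s)), s)
})

test_that("unknown item types and unknown fields are schema errors naming the field", {
  bad_type <- '{"study_code":"X","title":"T","interventions":[{"id":"a","name":"A",
    "modules":[{"id":"m","title":"M","items":[
      {"id":"q","item_type":"hologram","prompt":"?"}]}]}]}'
  expect_error(load_study(bad_type), "item_type.*hologram|hologram")
  bad_field <- '{"study_code":"X","title":"T","frobnicate":1,"interventions":[]}'
  expect_error(load_study(bad_field), "frobnicate")
  expect_error(load_study('{"study_code":"X","interventions":[]}'), "title")
})

test_that("YAML is an alternate surface syntax of the same schema", {
  y <- "
study_code: YML1
title: Yaml study
interventions:
  - id: arm
    name: Arm
    modules:
      - id: m1
        title: Module
        items:
          - id: q1
            item_type: number_input
            prompt: 'Hours slept?'
            variable: sleep
        opening_rules:
          - rule: relative_to_intervention_start
            offset_minutes: 60
"
  s <- load_study(y, format = "yaml")
  expect_identical(s, load_study(save_study(s)))
  expect_equal(s$interventions[[1]]$modules[[1]]$opening_rules[[1]]$offset_minutes, 60L)
})

test_that("serialization is byte-stable and preserves unicode prompts", {
  s <- study_definition("UNI1", "Unicode étude", list(
    intervention("arm", "Arm", list(
      study_module("m1", "Mödul", list(
        item("q1", "open_text", "Ça va bien? ☃")),
        opening_rules = list(open_after_enrollment(0)))
    ))))
  j1 <- save_study(s); j2 <- save_study(load_study(j1))
  expect_identical(j1, j2)
  expect_equal(load_study(j1)$interventions[[1]]$modules[[1]]$items[[1]]$prompt,
               "Ça va bien? ☃")
})

test_that("randomly generated valid studies round-trip through save/load", {
  for (seed in 1:25) {
    s <- random_study(seed)
    expect_identical(load_study(save_study(s)), s, label = paste("seed", seed))
    expect_identical(load_study(save_study(s), format = "yaml"), s,
                     label = paste("yaml sniff seed", seed))
  }
})

test_that("the packaged self-reflection example loads and validates clean", {
  path <- system.file("extdata", "self_reflection.study.json", package = "emaflow")
  expect_true(nzchar(path))
  s <- load_study(path)
  expect_identical(s, example_study())
  expect_equal(nrow(validate_study(s)), 0)
  expect_length(s$interventions[[1]]$modules, 3)
})

test_that("notification cardinality is enforced: one opening, one closing", {
  m <- study_module("m1", "M", list(item("q1", "slider", "?", variable = "v")),
                    opening_rules = list(open_after_enrollment(0)),
                    notifications = list(notify_opening("a"), notify_opening("b")))
  s <- study_definition("S1", "T", list(intervention("arm", "A", list(m))))
  v <- validate_study(s)
  expect_equal(v$code, "NOTIF_CARDINALITY")
  expect_match(v$path, "notifications")

  m2 <- study_module("m1", "M", list(item("q1", "slider", "?", variable = "v")),
                     opening_rules = list(open_after_enrollment(0)),
                     closing_rules = list(close_after_open(60)),
                     notifications = list(notify_opening(), notify_closing()))
  s2 <- study_definition("S2", "T", list(intervention("arm", "A", list(m2))))
  expect_equal(nrow(validate_study(s2)), 0)
})

test_that("closing notifications need a predictable closing rule", {
  m <- study_module("m1", "M", list(item("q1", "slider", "?", variable = "v")),
                    opening_rules = list(open_after_enrollment(0)),
                    closing_rules = list(close_on_answer("q1", "ge", 5)),
                    notifications = list(notify_closing()))
  s <- study_definition("S1", "T", list(intervention("arm", "A", list(m))))
  expect_true("CLOSING_NOTIF_INCOMPATIBLE" %in% validate_study(s)$code)
})

test_that("validator flags dangling references, bad comparators and info-item variables", {
  m <- study_module("m1", "M",
                    list(item("i1", "info_content", "welcome"),
                         item("q1", "text_field", "name?", variable = "nm")),
                    opening_rules = list(open_after_completion("nope", 10),
                                         open_on_answer("q1", "ge", 3)))
  s <- study_definition("S1", "T", list(intervention("arm", "A", list(m))))
  v <- validate_study(s)
  expect_true("DANGLING_REF" %in% v$code)      # module 'nope'
  expect_true("BAD_COMPARATOR" %in% v$code)    # ge on a text item

  bad_info <- study_definition("S2", "T", list(intervention("arm", "A", list(
    study_module("m1", "M", list(
      item("i1", "info_content", "welcome", variable = "x")),
      opening_rules = list(open_after_enrollment(0)))))))
  expect_true("INFO_ITEM_VARIABLE" %in% validate_study(bad_info)$code)
})

test_that("validator checks calculated variables parse and aggregate numerics", {
  iv <- intervention("arm", "A", list(
    study_module("m1", "M", list(
      item("q1", "slider", "?", variable = "num_v"),
      item("q2", "text_field", "?", variable = "txt_v")))),
    calc_variables = list(calc_variable("good", "SUM_ANS(num_v) + 1"),
                          calc_variable("bad_parse", "1 + * 2"),
                          calc_variable("bad_agg", "SUM_ANS(txt_v)"),
                          calc_variable("bad_ref", "MODE_ANS(ghost)")))
  v <- validate_study(study_definition("S1", "T", list(iv)))
  expect_true("EXPR_SYNTAX" %in% v$code)
  expect_true("AGG_NON_NUMERIC" %in% v$code)
  expect_true("DANGLING_REF" %in% v$code)
})

test_that("adding a violating element never removes existing violations", {
  base_mod <- study_module("m1", "M", list(item("q1", "slider", "?", variable = "v")),
                           opening_rules = list(open_after_enrollment(0)),
                           notifications = list(notify_opening(), notify_opening()))
  s1 <- study_definition("S1", "T", list(intervention("arm", "A", list(base_mod))))
  v1 <- validate_study(s1)
  worse_mod <- study_module("m2", "M2", list(item("q1", "slider", "?", variable = "v2")),
                            opening_rules = list(open_after_completion("ghost", 5)))
  s2 <- study_definition("S1", "T", list(intervention("arm", "A",
                                                      list(base_mod, worse_mod))))
  v2 <- validate_study(s2)
  expect_true(nrow(v2) > nrow(v1))
  expect_true(all(paste(v1$code, v1$path) %in% paste(v2$code, v2$path)))
})

test_that("violations are stable-ordered by path", {
  for (seed in 1:5) {
    s <- random_study(seed)
    v <- validate_study(s)
    expect_identical(v$path, sort(v$path, method = "radix"))
  }
})
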