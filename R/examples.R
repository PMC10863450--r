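# Packaged example studies. `example_study()` builds the three-module
# self-reflection programme shipped as inst/extdata/self_reflection.study.json;
# `minimal_study()` is the smallest useful study (one module, one slider).

#' Example studies
#'
#' `example_study()` returns a three-module self-reflection programme: a
#' welcome module open from enrollment, a daily check-in that opens a day
#' after the welcome is completed and closes 12 hours later (with a reminder
#' and a closing notification), and a support module that opens either when
#' the check-in reports low mood or when the check-in was left unfinished
#' for two days. The same study ships as
#' `system.file("extdata", "self_reflection.study.json", package = "emaflow")`.
#'
#' `minimal_study()` is a one-intervention, one-module, one-slider study,
#' convenient as a test scaffold.
#'
#' @return A [study_definition()].
#' @export
example_study <- function() {
  study_definition(
    "SELFREF1", "Self-reflection coaching example",
    list(intervention(
      "core", "Core programme",
      modules = list(
        study_module(
          "m_welcome", "Welcome and baseline",
          items = list(
            item("i_intro", "info_content",
                 "Welcome! Over the next days we will check in on your mood."),
            item("q_mood0", "slider", "How is your mood right now? (1-10)",
                 variable = "mood_baseline")
          ),
          opening_rules = list(open_after_enrollment(0)),
          notifications = list(notify_opening("Your programme has started"))
        ),
        study_module(
          "m_checkin", "Daily mood check-in",
          items = list(
            item("q_mood1", "slider", "How is your mood today? (1-10)",
                 variable = "mood_today"),
            item("q_sleep1", "number_input", "How many hours did you sleep?",
                 variable = "sleep_hours")
          ),
          opening_rules = list(open_after_completion("m_welcome", 1440)),
          closing_rules = list(close_after_open(720)),
          notifications = list(
            notify_opening("Time for your daily check-in"),
            notify_reminder("Your check-in is still waiting"),
            notify_closing("Your check-in closes in 15 minutes")
          )
        ),
        study_module(
          "m_support", "Support and reflection",
          items = list(
            item("i_support", "info_content",
                 "A dip is normal. Here are three things that can help."),
            item("q_reflect", "text_field", "What would help you most right now?",
                 variable = "reflection")
          ),
          opening_rules = list(
            open_on_answer("q_mood1", "le", 4),
            open_if_not_finished("m_checkin", 2880)
          )
        )
      ),
      calc_variables = list(
        calc_variable("cohort_mood_mean",
                      "SUM_ANS(mood_today) / NUM_P_ANS(mood_today)"),
        calc_variable("low_mood_count", "COUNT_ANS(mood_today, 1) + COUNT_ANS(mood_today, 2)")
      )
    ))
  )
}

#' @rdname example_study
#' @export
minimal_study <- function() {
  study_definition(
    "MINI1", "Minimal study",
    list(intervention("arm", "Single arm", list(
      study_module("m1", "Check-in",
                   items = list(item("q1", "slider", "How do you feel? (1-10)",
                                     variable = "mood")),
                   opening_rules = list(open_after_enrollment(0)))
    )))
  )
}
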