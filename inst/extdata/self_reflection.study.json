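{
  "schema_version": 1,
  "study_code": "SELFREF1",
  "title": "Self-reflection coaching example",
  "interventions": [
    {
      "id": "core",
      "name": "Core programme",
      "assignment_policy": "auto_assign",
      "calc_variables": [
        {
          "name": "cohort_mood_mean",
          "expression": "SUM_ANS(mood_today) / NUM_P_ANS(mood_today)"
        },
        {
          "name": "low_mood_count",
          "expression": "COUNT_ANS(mood_today, 1) + COUNT_ANS(mood_today, 2)"
        }
      ],
      "modules": [
        {
          "id": "m_welcome",
          "title": "Welcome and baseline",
          "items": [
            {
              "id": "i_intro",
              "item_type": "info_content",
              "prompt": "Welcome! Over the next days we will check in on your mood.",
              "variable": null,
              "options": null,
              "media_ref": null
            },
            {
              "id": "q_mood0",
              "item_type": "slider",
              "prompt": "How is your mood right now? (1-10)",
              "variable": "mood_baseline",
              "options": null,
              "media_ref": null
            }
          ],
          "opening_rules": [
            {
              "rule": "relative_to_intervention_start",
              "offset_minutes": 0
            }
          ],
          "closing_rules": [],
          "notifications": [
            {
              "kind": "opening",
              "trigger": {
                "type": "interval_after_open",
                "offset_minutes": 0
              },
              "text": "Your programme has started"
            }
          ]
        },
        {
          "id": "m_checkin",
          "title": "Daily mood check-in",
          "items": [
            {
              "id": "q_mood1",
              "item_type": "slider",
              "prompt": "How is your mood today? (1-10)",
              "variable": "mood_today",
              "options": null,
              "media_ref": null
            },
            {
              "id": "q_sleep1",
              "item_type": "number_input",
              "prompt": "How many hours did you sleep?",
              "variable": "sleep_hours",
              "options": null,
              "media_ref": null
            }
          ],
          "opening_rules": [
            {
              "rule": "relative_to_module_completion",
              "ref_module_id": "m_welcome",
              "offset_minutes": 1440
            }
          ],
          "closing_rules": [
            {
              "rule": "relative_to_module_start",
              "offset_minutes": 720
            }
          ],
          "notifications": [
            {
              "kind": "opening",
              "trigger": {
                "type": "interval_after_open",
                "offset_minutes": 0
              },
              "text": "Time for your daily check-in"
            },
            {
              "kind": "reminder",
              "trigger": {
                "type": "interval_after_open",
                "offset_minutes": 15
              },
              "text": "Your check-in is still waiting"
            },
            {
              "kind": "closing",
              "trigger": {
                "type": "closing_lead"
              },
              "text": "Your check-in closes in 15 minutes"
            }
          ]
        },
        {
          "id": "m_support",
          "title": "Support and reflection",
          "items": [
            {
              "id": "i_support",
              "item_type": "info_content",
              "prompt": "A dip is normal. Here are three things that can help.",
              "variable": null,
              "options": null,
              "media_ref": null
            },
            {
              "id": "q_reflect",
              "item_type": "text_field",
              "prompt": "What would help you most right now?",
              "variable": "reflection",
              "options": null,
              "media_ref": null
            }
          ],
          "opening_rules": [
            {
              "rule": "answer_condition",
              "ref_item_id": "q_mood1",
              "comparator": "le",
              "value": 4
            },
            {
              "rule": "on_module_not_finished",
              "ref_module_id": "m_checkin",
              "check_offset_minutes": 2880
            }
          ],
          "closing_rules": [],
          "notifications": []
        }
      ]
    }
  ]
}
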