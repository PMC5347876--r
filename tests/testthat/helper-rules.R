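# One minimal episode state per rule-table row, paired with the interval the
# table prints for it. Used both for row-by-row fidelity checks and for
# enumeration-based properties.
rule_table_cases <- function() {
  list(
    list(id = "diagnosis", months = 2,
         state = list(within_month_of_diagnosis = TRUE)),
    list(id = "aids", months = 2, state = list(aids_event = TRUE)),
    list(id = "art_start", months = 2, state = list(started_art = TRUE)),
    list(id = "art_switch", months = 2,
         state = list(started_combination = TRUE)),
    list(id = "cd4_le350_drop", months = 2,
         state = list(on_art = FALSE, lowest_cd4 = 300, cd4_drop = 40)),
    list(id = "cd4_le350_stable", months = 4,
         state = list(on_art = FALSE, lowest_cd4 = 300, cd4_drop = -10)),
    list(id = "cd4_351_499", months = 4,
         state = list(on_art = FALSE, lowest_cd4 = 420)),
    list(id = "cd4_ge500_drop_ge100", months = 4,
         state = list(on_art = FALSE, lowest_cd4 = 600, cd4_drop = 150)),
    list(id = "cd4_ge500_high_vl", months = 4,
         state = list(on_art = FALSE, lowest_cd4 = 600, cd4_drop = 50,
                      highest_vl = 150000)),
    list(id = "cd4_ge500_low_vl", months = 6,
         state = list(on_art = FALSE, lowest_cd4 = 600, cd4_drop = 50,
                      highest_vl = 30000)),
    list(id = "vl_gt200", months = 2,
         state = list(on_art = TRUE, highest_vl = 5000)),
    list(id = "vl_low_not_blip", months = 2,
         state = list(on_art = TRUE, highest_vl = 120, vl_is_blip = FALSE)),
    list(id = "vl_low_blip", months = 4,
         state = list(on_art = TRUE, highest_vl = 120, vl_is_blip = TRUE)),
    list(id = "vl_supp_cd4_le200", months = 4,
         state = list(on_art = TRUE, highest_vl = 40, lowest_cd4 = 180)),
    list(id = "vl_supp_cd4_gt200", months = 6,
         state = list(on_art = TRUE, highest_vl = 40, lowest_cd4 = 420)))
}
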