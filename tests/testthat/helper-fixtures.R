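# shared fixtures built in code

inverted_schedule <- function() light_schedule("20:00", "08:00")

shifted_schedule <- function() {
  light_schedule("20:00", "08:00",
                 shifts = schedule_shift(day = 3, at = "08:00", offset_h = -6))
}

# deterministic trace: one event at each given second
grid_trace <- function(times, id = "animal") {
  tibble::tibble(animal_id = id, time_s = as.numeric(times))
}

# a tiny valid event log with k records one second apart, channel 1
tiny_log <- function(k = 3) {
  log_events(cage_array(list("1" = seq_len(k))), seed = 1)
}
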