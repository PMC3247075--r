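# Shared constants: the four study data types, review statuses, the wide
# payload column set and the per-type required/optional payload fields.

DATA_TYPES <- c("dichotomous", "continuous", "generic", "oe_variance")
REVIEW_STATUSES <- c("full", "protocol", "withdrawn")

PAYLOAD_COLS <- c(
  "events_1", "total_1", "events_2", "total_2",
  "n_1", "mean_1", "sd_1", "n_2", "mean_2", "sd_2",
  "estimate", "standard_error",
  "o_minus_e", "variance",
  "total_n"
)

# payload columns that must be non-NA for each data type
REQUIRED_PAYLOAD <- list(
  dichotomous = c("events_1", "total_1", "events_2", "total_2"),
  continuous  = c("n_1", "mean_1", "sd_1", "n_2", "mean_2", "sd_2"),
  generic     = c("estimate", "standard_error"),
  oe_variance = c("o_minus_e", "variance")
)
# optional extras (anything else must be NA)
OPTIONAL_PAYLOAD <- list(
  dichotomous = character(0),
  continuous  = character(0),
  generic     = "total_n",
  oe_variance = "total_n"
)

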