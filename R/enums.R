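# Canonical vocabularies of the case-report model. Raw file codes are
# normalized onto these at parse time; anything unrecognized maps to
# "unknown" rather than erroring, since SRS files are notoriously dirty.

srs_sexes <- c("male", "female", "unknown")

srs_roles <- c("primary_suspect", "secondary_suspect", "concomitant",
               "interacting", "unknown")

srs_reporters <- c("physician", "pharmacist", "consumer",
                   "other_health_professional", "unknown")

srs_outcomes <- c("death", "life_threatening", "hospitalization",
                  "disability", "congenital_anomaly", "other")

# age bins mirror the row structure of the descriptive tables each
# database conventionally reports
faers_age_bins <- c("<2", "2-11", "12-17", "18-64", "65-85", ">85", "unknown")
jader_age_bins <- c("<10", "10-19", "20-69", ">=70", "unknown")

faers_role_codes     <- c(PS = "primary_suspect", SS = "secondary_suspect",
                          C = "concomitant", I = "interacting")
faers_reporter_codes <- c(MD = "physician", PH = "pharmacist", CN = "consumer",
                          OT = "other_health_professional",
                          HP = "other_health_professional")
faers_outcome_codes  <- c(DE = "death", LT = "life_threatening",
                          HO = "hospitalization", DS = "disability",
                          CA = "congenital_anomaly", OT = "other")

jader_sex_codes      <- c("男性" = "male", "女性" = "female")
jader_role_codes     <- c("被疑薬" = "primary_suspect",
                          "併用薬" = "concomitant",
                          "相互作用" = "interacting")
jader_reporter_codes <- c("医師" = "physician",
                          "薬剤師" = "pharmacist")
# JADER outcome field: death vs everything else is the only distinction
# the common descriptive tables make
jader_death_code <- "死亡"

bin_age_faers <- function(age_years) {
  dplyr::case_when(
    is.na(age_years)  ~ "unknown",
    age_years < 2     ~ "<2",
    age_years < 12    ~ "2-11",
    age_years < 18    ~ "12-17",
    age_years < 65    ~ "18-64",
    age_years <= 85   ~ "65-85",
    TRUE              ~ ">85"
  )
}

bin_age_jader <- function(decade) {
  # decade = lower bound of the reported 10-year band (NA if unreported)
  dplyr::case_when(
    is.na(decade) ~ "unknown",
    decade < 10   ~ "<10",
    decade < 20   ~ "10-19",
    decade < 70   ~ "20-69",
    TRUE          ~ ">=70"
  )
}
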