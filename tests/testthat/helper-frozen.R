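# Frozen expected values for the reference cohort, computed once with an
# independent brute-force oracle (manual transforms, pooled moments,
# consecutive-pair enumeration, solve()-based distances) and pinned here.

frozen_mmd <- tibble::tibble(
  patient_id = c("r1", "r1", "r1", "r2", "r2", "r3", "r4", "r5", "r6"),
  date = as.Date(c(14628, 15028, 15328, 14629, 14928, 14627, 14628, 14656,
                   14630), origin = "1970-01-01"),
  gap_days = c(14L, 14L, 14L, 15L, 14L, 13L, 14L, 14L, 16L),
  mmd = c(0, 2.2030152075366889, 4.2676923580360375, 2.6108060642328699,
          2.3548008624307037, 2.5419482832216018, 2.3234120266987919,
          2.7275707947275585, 2.3027751362724151),
  zero_replaced = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE),
  log_mmd = c(0.096679790339788463, 0.78982697089973375,
              1.4510732497815699, 0.95965901052514369,
              0.85645616441561878, 0.93293082764354396,
              0.84303680641972378, 1.0034113942920198,
              0.83411497658926959)
)

frozen_trend <- list(bin = c(1, 2, 5),
                     mean = c(2.96462650700241, 2.20301520753669, 0),
                     n = c(3L, 1L, 1L))

frozen_rows <- tibble::tibble(
  patient_id = c("r1", "r1", "r1", "r2", "r2", "r3", "r4", "r5", "r6"),
  start = c(0.038329911019849415, 1.1334702258726899, 1.9548254620123204,
            0.041067761806981518, 0.85968514715947986,
            0.035592060232717319, 0.038329911019849415,
            0.11498973305954825, 0.04380561259411362),
  stop = c(1.1334702258726899, 1.9548254620123204, 2.0807665982203969,
           0.85968514715947986, 0.9308692676249144, 0.13689253935660506,
           0.16427104722792607, 0.21902806297056809,
           0.082135523613963035),
  event = c(0L, 0L, 1L, 0L, 0L, 0L, 1L, 0L, 1L)
)

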