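# Shared fixture builders; everything is generated in code at test time.

table2_schedule <- function() make_frame_schedule(list(c(12, 10), c(6, 30), c(10, 240)))

# a noiseless phantom rendered once per test file at most
quiet_phantom <- function(...) phantom_spec(pet_noise = 0, mr_sigma = 0, ...)

# full lesion table at a single grade for every cell
uniform_score_table <- function(n_subjects, cartilage, bme, rater = "A") {
  df <- expand.grid(subject = seq_len(n_subjects),
                    subregion = hip_subregions(),
                    stringsAsFactors = FALSE)
  df$rater <- rater
  df$cartilage_grade <- cartilage
  df$bme_grade <- bme
  lesion_score_table(df)
}

# surfaces-in-different-poses helper
rigid_move <- function(surface, angles = c(0.3, -0.2, 0.5), shift = c(10, -4, 7)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  out <- surface %*% t(Rz %*% Ry %*% Rx)
  out <- sweep(out, 2, shift, "+")
  attr(out, "part") <- attr(surface, "part")
  out
}
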