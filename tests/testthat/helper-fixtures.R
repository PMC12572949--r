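# Fixtures built in code: flat segmentations, standard phantoms and the
# independent quadrature oracle used against the geometry pipeline.

flat_seg <- function(width = 38.4, thickness = 3, notch_x = width / 2,
                     n = 101L, y0 = 10) {
  x <- seq(0, width, length.out = n)
  cartilage_segmentation(cbind(x, y0), cbind(x, y0 - thickness),
                         notch_point = c(notch_x, y0), image_id = "flat")
}

# Three-plateau thickness profile (3.5 | 2.9 | 3.3 mm) with short linear
# blending ramps near the plateau borders; continuous and piecewise linear,
# so a polyline sampled on a grid containing the kinks represents it exactly.
piecewise_breaks <- c(12.4, 13.2, 25.2, 26.0)
piecewise_profile <- function(x) {
  approx(x = c(0, piecewise_breaks, 38.4),
         y = c(3.5, 3.5, 2.9, 2.9, 3.3, 3.3), xout = x)$y
}

# Independent oracle: zone thickness of a flat-bone phantom is the profile
# average over the zone, by quadrature on the profile alone (no package
# geometry code involved). Integration is split at the profile kinks.
oracle_flat_zone_thickness <- function(profile, lo, hi,
                                       breaks = piecewise_breaks) {
  cuts <- sort(unique(c(lo, hi, breaks[breaks > lo & breaks < hi])))
  area <- sum(vapply(seq_len(length(cuts) - 1L), function(i)
    stats::integrate(profile, cuts[i], cuts[i + 1L], rel.tol = 1e-12,
                     subdivisions = 1000L)$value, numeric(1)))
  area / (hi - lo)
}

# Cohort groups data frame matching the bundled age-group male table,
# right medial site.
male_right_medial_groups <- function() {
  data.frame(age_group = c("young", "middle_aged", "older", "retirement"),
             site = "medial", side = "right",
             mean_mm = c(3.361, 3.370, 3.427, 3.678),
             sd_mm = c(0.403, 0.285, 0.437, 0.383),
             n = c(23L, 27L, 22L, 28L))
}
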