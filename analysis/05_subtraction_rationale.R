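#!/usr/bin/env Rscript
# Why subtract the median-filtered image before thresholding? Under PSF blur
# a direct threshold of the raw image inflates vesicle footprints (the halo
# passes the threshold). This script quantifies the effect on 20 scenes with
# a deliberately heavy 3-px PSF: mean segmented area of the
# median-subtraction pipeline vs direct Otsu on the raw image, each against
# the true mean disk area.

library(endoquant)

rows <- lapply(1:20, function(s) {
  scn <- generate_scene(scene_config(n_green = 40, placement = "scattered",
                                     psf_sigma_nm = 300, seed = 3000 + s))
  img <- to_8bit(max_projection(scn$stack, "green"))
  true_area <- mean(pi * scn$truth$objects$radius_nm^2)
  med <- segment_channel(img, seg_config(), "green")
  a_med <- mean(measure_objects(med, img)$area_nm2)
  raw <- extract_objects(binarize(img, select_threshold(img, img, "otsu")),
                         20000, "green")
  a_raw <- mean(measure_objects(raw, img)$area_nm2)
  data.frame(seed = 3000 + s, true_area_nm2 = true_area,
             medsub_area_nm2 = a_med, otsu_area_nm2 = a_raw,
             medsub_wins = abs(a_med - true_area) < abs(a_raw - true_area))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/subtraction_rationale.csv", row.names = FALSE)

cat(sprintf("mean true disk area: %.0f nm^2\n", mean(tab$true_area_nm2)))
cat(sprintf("mean segmented area, median-subtraction: %.0f nm^2\n",
            mean(tab$medsub_area_nm2)))
cat(sprintf("mean segmented area, raw Otsu:           %.0f nm^2\n",
            mean(tab$otsu_area_nm2)))
cat(sprintf("median-subtraction closer to truth in %d/%d scenes\n",
            sum(tab$medsub_wins), nrow(tab)))
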