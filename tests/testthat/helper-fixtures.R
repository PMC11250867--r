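# write a matched WT/KO image pair to disk and return its manifest rows
write_pair_fixture <- function(dir, amp, seed, id) {
  pair <- make_wt_ko_pair(simulate_snr_scene(amp, n_nuclei = 9, seed = seed))
  wt_path <- file.path(dir, paste0(id, "_wt.png"))
  ko_path <- file.path(dir, paste0(id, "_ko.png"))
  write_rgb_image(pair$wt, wt_path)
  write_rgb_image(pair$ko, ko_path)
  tibble::tibble(sample_id = paste0(id, c("_wt", "_ko")),
                 image = c(wt_path, ko_path),
                 pair_id = id, role = c("wt", "ko"))
}
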