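Package: beanhis
Title: High-Impact Spot Mapping of Climate Change Effects on Drybean Yields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatial pipeline for assessing where climate change will hit
    drybean (Phaseolus vulgaris) production hardest. Downscales coarse
    climate-model monthly anomalies onto a fine baseline climatology with the
    delta method, generates replicate years of daily weather with a
    Markov-chain/gamma stochastic generator, simulates seasonal yields with a
    simplified water- and temperature-limited crop emulator under a factorial
    management design, classifies pixels into hotspots, adaptation spots and
    pressure spots from robustly scaled yield-change deviations or local
    Getis-Ord statistics, selects study sites near producing communities, and
    quantifies climate-model ensemble uncertainty. Ships a synthetic-data
    generator emulating tropical bimodal-rainfall climatologies so the whole
    pipeline runs without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
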