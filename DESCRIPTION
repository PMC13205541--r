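Package: fviq
Title: Quantification of Facial Vitiligo from Wood's-Light Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Semi-automatic quantification of facial vitiligo from Wood's-light
    photographs. Operator-drawn polygonal regions of interest are refined to
    pixel level by contrast enhancement (channel combination plus
    contrast-limited adaptive histogram equalisation) and per-region
    thresholding; the detected patch area is normalised by face area and
    averaged over facial views to give the Face Vitiligo Index (FVI).
    Also provides fingertip-unit F-VASI estimation, scoring of the vDLQI and
    VitiQoL quality-of-life instruments, longitudinal percent-change reports,
    and a synthetic Wood's-light face generator with ground-truth masks for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jpeg,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
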