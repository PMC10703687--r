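Package: gradepi
Title: Gradient-Coil Performance Modeling for High-Resolution Echo-Planar MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the acquisition physics that determine what a head
    gradient coil buys in echo-planar imaging (EPI): minimum echo spacing
    and echo time under amplitude/slew/duty-cycle limits with forbidden
    mechanical-resonance bands, T2*-driven point-spread-function blurring,
    closed-form SNR scalings, Stejskal-Tanner diffusion-encoding timing,
    SAFE-style peripheral-nerve-stimulation supervision of gradient
    waveforms, synthetic multi-channel receive-array SNR and retained-SNR
    (1/g) mapping, and susceptibility distortion forward modeling and warp
    estimation from reversed phase-encode pairs.  Ships the coil presets,
    digital brain phantoms and multi-coil simulators needed to recompute
    the comparisons on a desktop.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, jsonlite, RNifti
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
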