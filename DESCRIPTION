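Package: uclstrain
Title: Rigid-Body Strain Simulation of the Elbow Ulnar Collateral
    Ligament and Flexor-Pronator Common Tendons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes percent strain of the fiber bundles of the elbow
    ulnar collateral ligament (anterior and posterior bundles) and of the
    anterior and posterior common tendons of the flexor-pronator muscles
    during simulated elbow flexion-extension and valgus rotation.  From
    3-D digitized bony and soft-tissue landmarks it fits the glenohumeral
    rotation center by least-squares sphere fitting, constructs a
    humerus-fixed anatomical coordinate frame, rigidly poses the
    ulna-fixed attachment points over a flexion-by-valgus grid, and
    reports per-fiber and average strain relative to the reference pose
    of 90 degrees flexion and 0 degrees valgus.  Includes a seeded
    generator of anatomically plausible synthetic specimens for the three
    published morphology groups of these structures, landmark file I/O,
    and command-line style reporting of long and wide strain tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
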