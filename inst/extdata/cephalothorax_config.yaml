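# Cephalothorax landmark map: synthetic reconstruction of the 33-landmark
# scheme (30 paired + 3 on the axis of bilateral symmetry). Pair labels match
# the published pair names (e.g. 26-04, 31-29); module memberships of the
# anatomical hypotheses are reconstructed from the anatomical descriptions,
# not from digitized coordinates. Indices are 1-based; pairs are listed
# [left, right] in anterior-to-posterior (cephalocaudal) order.
landmarks: 33
pairs:
  - [28, 2]    # orbital sinus
  - [27, 3]    # rostral spine base
  - [26, 4]    # anterolateral spine tip
  - [25, 5]    # hepatic lobe 1
  - [24, 6]    # hepatic area
  - [23, 7]    # hepatic lobe 2 tip
  - [22, 8]    # hepatic lobe 3 tip
  - [31, 29]   # cervical groove inflection
  - [21, 9]    # anterior branchial line
  - [20, 10]   # epibranchial spine tip
  - [19, 11]   # branchial area
  - [18, 12]   # branchial line x linea aeglica lateralis
  - [17, 13]   # distal branchial area
  - [16, 14]   # posterior branchial line
  - [32, 30]   # posterolateral margin
midline: [1, 15, 33]   # rostral tip, cardiac center, posterior margin
axis_reference: 1
longitudinal_order: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15]
partitions:
  - name: uniform
    modules:
      whole: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18,
              19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33]
  - name: developmental          # cephalic vs thoracic, split at cervical groove
    modules:
      cephalic: [1, 2, 3, 4, 5, 6, 7, 8, 22, 23, 24, 25, 26, 27, 28]
      thoracic: [9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 29, 30,
                 31, 32, 33]
  - name: gonadic                # dorsal area over the ovarian space
    modules:
      gonadic: [9, 10, 11, 12, 15, 18, 19, 20, 21, 33]
      rest: [1, 2, 3, 4, 5, 6, 7, 8, 13, 14, 16, 17, 22, 23, 24, 25, 26, 27,
             28, 29, 30, 31, 32]
  - name: agonistic              # frontal and lateral spiny processes
    modules:
      agonistic: [1, 2, 3, 4, 5, 25, 26, 27, 28, 29, 31]
      rest: [6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22,
             23, 24, 30, 32, 33]
  - name: anatomical_I           # cephalic + thoracic split in two
    modules:
      cephalic: [1, 2, 3, 4, 5, 6, 7, 8, 22, 23, 24, 25, 26, 27, 28]
      anterior_thoracic: [9, 10, 15, 20, 21, 29, 31]
      posterior_thoracic: [11, 12, 13, 14, 16, 17, 18, 19, 30, 32, 33]
  - name: anatomical_II          # cephalic split + thoracic split
    modules:
      frontal: [1, 2, 3, 4, 26, 27, 28]
      hepatic: [5, 6, 7, 8, 22, 23, 24, 25]
      anterior_thoracic: [9, 10, 15, 20, 21, 29, 31]
      posterior_thoracic: [11, 12, 13, 14, 16, 17, 18, 19, 30, 32, 33]
  - name: anatomical_III         # all dorsal-line subdivisions
    modules:
      frontal: [1, 2, 3, 4, 26, 27, 28]
      hepatic: [5, 6, 7, 8, 22, 23, 24, 25]
      cardiac: [15, 29, 31, 33]
      branchial: [9, 10, 11, 12, 17, 18, 19, 20, 21]
      posterior: [13, 14, 16, 30, 32]
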