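# Editable measurement-definition template. Landmark names are placeholders
# matching the synthetic skull template (mouse_skull_template()); replace them
# with your own digitised landmark names as needed. Planes: axial = superior
# view (x-y), sagittal = lateral view (y-z), coronal = frontal view (x-z).
measurements:
  - name: facial_length
    type: distance
    landmarks: [nasale, nasion]
  - name: skull_length
    type: distance
    landmarks: [nasale, opisthion]
  - name: bo_length          # basioccipital
    type: distance
    landmarks: [basion, sos]
  - name: bs_length          # basisphenoid
    type: distance
    landmarks: [sos, iss]
  - name: ps_length          # presphenoid
    type: distance
    landmarks: [iss, presphenoid_ant]
  - name: eth_length         # ethmoid
    type: distance
    landmarks: [ethmoid_post, ethmoid_ant]
  - name: nasal_width
    type: distance
    landmarks: [nasal_lateral_l, nasal_lateral_r]
  - name: cranial_base_1     # flexion at the spheno-occipital synchondrosis
    type: angle3
    landmarks: [sos, basion, iss]
    plane: sagittal
  - name: cranial_base_2     # flexion at the intersphenoid synchondrosis
    type: angle3
    landmarks: [iss, sos, presphenoid_ant]
    plane: sagittal
  - name: snout_angle
    type: angle3
    landmarks: [nasion, nasale, bregma]
    plane: sagittal
  - name: frontal_bossing_angle
    type: angle3
    landmarks: [bregma, nasion, lambda]
    plane: sagittal
  - name: nasal_depression_avg   # mean of left and right, superior view
    type: bilateral_angle
    left:
      name: nasal_depression_l
      type: angle3
      landmarks: [nasal_lateral_l, nasale, frontal_l]
      plane: axial
    right:
      name: nasal_depression_r
      type: angle3
      landmarks: [nasal_lateral_r, nasale, frontal_r]
      plane: axial
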