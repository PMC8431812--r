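# a T-shaped fixture projects to the pinned image

    Code
      print(project_patch(m, axis = c(0, 0, 1), spacing = 1))
    Output
      <patch_image> 6x6 pixels at 1 A/px
      ..oo..
      ..oo..
      ..oo..
      ..oo..
      ######
      ######

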