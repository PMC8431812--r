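# the full verdict table is pinned

    Code
      print(attraction_table())
    Output
        A C D E F G H I K L M N P Q R S T V W Y
      A 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 1 1 1 1
      C 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 1 1 1 1
      D 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
      E 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 0 1 1 1
      F 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 1 1 1 1
      G 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
      H 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 0 1 1 1
      I 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 1 1 1 1
      K 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 0 1 1 1
      L 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 1 1 1 1
      M 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 1 1 1 1
      N 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
      P 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
      Q 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 0 1 1 1
      R 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 0 1 1 1
      S 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
      T 1 1 0 0 1 0 0 1 0 1 1 0 0 0 0 0 0 1 1 1
      V 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 1 1 1 1
      W 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 1 1 1 1
      Y 1 1 0 1 1 0 1 1 1 1 1 0 0 1 1 0 1 1 1 1

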