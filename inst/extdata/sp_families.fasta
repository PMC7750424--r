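>Vk1|Vk1|light
MDMRVPAQLLGLLLLWLPGARC
>Vk2|Vk2|light
MRLPAQLLGLLMLWVPGSSA
>Vk3|Vk3|light
MEAPAQLLFLLLLWLPDTTG
>Vk4|Vk4|light
MVLQTQVFISLLLWISGAYG
>Vk5|Vk5|light
MGSQVHLLSFLLLWISDTRA
>Vk6|Vk6|light
MLPSQLIGFLLLWVPASRG
>VH1|VH1|heavy
MDWTWRILFLVAAATGAHS
>VH2|VH2|heavy
MDILCSTLLLLTVPSWVLS
>VH3|VH3|heavy
MEFGLSWVFLVAILKGVQC
>VH4|VH4|heavy
MKHLWFFLLLVAAPRWVLS
>VH5|VH5|heavy
MGSTAILALLLAVLQGVCS
>VH6|VH6|heavy
MSVSFLIFLPVLGLPWGVLS
>VH7|VH7|heavy
MDWTWRILFLVAAATGAHS
>IgE|IgE|heavy
MDWTWILFLVAAATRVHS
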