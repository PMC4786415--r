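>tcar0761_construct DUF3782 nonad-repeat region fused between trimerizing adaptors
ITLMQANMATKDDLARMATKDDIANMATKDDIANMATKDDIAKLDVKIENLNTK
>omp100_stalk TAA stalk fragment with the IENKADKAD nonad
IQNVDVRSTENAARSRANEQKIAENKKAIENKADKADVEKNRADIAANSRAIATFRSSSQNIAALTTK
>prophage_tailfiber_2c3f internal tandem beta-layer region
IDGLATKVETAQKLQQKADKETVYTKAESKQE
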