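>NW1_01
CTGCTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>NW1_02
CTGCTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>NW1_03
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>NW1_04
CTGCTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>NW1_05
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>NW1_06
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>NW1_07
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>NW1_08
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC1_01
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC1_02
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC1_03
CTACTTGACTTATTGATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC1_04
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCACATGAAGTAAAGCA
>CC1_05
CTACTTGACTTATTGATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC1_06
CTACTTGACTGATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCACATGAAGTAAAGCA
>CC1_07
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTGTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC1_08
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC1_09
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC1_10
CTACTTGACTTATTGATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC2_01
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC2_02
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCACATGAAGTAAAGCA
>CC2_03
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCACATGAAGTAAAGCA
>CC2_04
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC2_05
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC2_06
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC2_07
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC2_08
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC2_09
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CC2_10
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCACATGAAGTAAAGCA
>CE1_01
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CE1_02
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CE1_03
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CE1_04
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATTCATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CE1_05
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CE1_06
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CE1_07
CTGCTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAACTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
>CE1_08
CTACTTGACTTATTTATCACACGTAAATTTTGATTTTACAAAATCATAGGACGAAACTGATACATCTCAGATAATTACTTATAAATAATGGTGATGTATAATTAAAGATTTTTATTAATAGTTATCTTGAAATTAGGCGTATTGCTCATGAAGTAAAGCA
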