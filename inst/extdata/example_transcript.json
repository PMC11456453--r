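{
  "participant_id": "demo01",
  "responses": [
    {
      "image_id": 1,
      "utterances": [
        {
          "tokens": [
            {
              "surface": "他",
              "char_count": 1,
              "raw_tag": "Nh",
              "flags": []
            },
            {
              "surface": "呃",
              "char_count": 1,
              "raw_tag": "I",
              "flags": [
                "filled_pause"
              ]
            },
            {
              "surface": "泡",
              "char_count": 1,
              "raw_tag": "VC",
              "flags": []
            },
            {
              "surface": "泡",
              "char_count": 1,
              "raw_tag": "VC",
              "flags": [
                "repetition"
              ]
            },
            {
              "surface": "茶",
              "char_count": 1,
              "raw_tag": "Na",
              "flags": []
            }
          ],
          "trailing_pause_s": 2.5
        },
        {
          "tokens": [
            {
              "surface": "很",
              "char_count": 1,
              "raw_tag": "D",
              "flags": []
            },
            {
              "surface": "好喝",
              "char_count": 2,
              "raw_tag": "A",
              "flags": []
            }
          ]
        }
      ]
    },
    {
      "image_id": 2,
      "utterances": [
        {
          "tokens": [
            {
              "surface": "茶",
              "char_count": 1,
              "raw_tag": "Na",
              "flags": []
            },
            {
              "surface": "被",
              "char_count": 1,
              "raw_tag": "P",
              "flags": []
            },
            {
              "surface": "喝",
              "char_count": 1,
              "raw_tag": "VC",
              "flags": []
            },
            {
              "surface": "完",
              "char_count": 1,
              "raw_tag": "VC",
              "flags": []
            },
            {
              "surface": "了",
              "char_count": 1,
              "raw_tag": "T",
              "flags": []
            }
          ],
          "trailing_pause_s": 0.8
        },
        {
          "tokens": [
            {
              "surface": "大家",
              "char_count": 2,
              "raw_tag": "Na",
              "flags": []
            },
            {
              "surface": "聊天",
              "char_count": 2,
              "raw_tag": "VA",
              "flags": []
            }
          ]
        }
      ]
    }
  ]
}
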